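---
title: "Methylation-guided risk stratification: models, choices, limitations"
author: "methstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-guided risk stratification: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-risk prostate cancer (clinical stage >= T3a, biopsy Gleason 8-10, or
PSA > 20 ng/ml) is clinically heterogeneous: most patients do well after
radical prostatectomy, a minority progress to clinical failure (CF --
histologically or radiologically confirmed local recurrence or distant
metastasis). Promoter hypermethylation of *GSTP1*, *APC*, *RARB*, *PTGS2*
and *CCND2*, measured by quantitative multiplex methylation-specific PCR
(QM-MSP) as percent methylation `100 * M / (M + U)`, is highly
cancer-specific (near zero in benign hyperplasia) and may stratify risk
within the high-risk group. The package implements the full analysis chain:
quantification and QC, diagnostic accuracy, functional-form exploration of
the marker-hazard relationship, optimal cutpoint discovery, prognostic Cox
models, and cross-validated comparison of clinical models with and without
the methylation term.

The striking substantive feature is that the marker-risk relationship is
*U-shaped*: patients with either low (< 15%) or high (> 50%) *GSTP1*
methylation fail sooner than the moderately methylated majority. Risk
models therefore use the trichotomy LM / MM / HM and the contrast
"MM vs LM+HM", not a linear methylation term.

## The synthetic cohort: what it emulates and what it does not

Patient-level data for this kind of study are generally not deposited, so
the package ships a generator (`simulate_cohort()`) whose defaults define
the study conditions all calibration tests run under:

* **Methylation marginals.** Each gene's percent methylation is a
  zero-inflated scaled-Beta mixture: a point mass at 0 (no methylated
  template detected) plus `100 * Beta(a, b)`. Benign defaults use a 0.90
  zero mass and a small-mean tail so the per-gene cohort mean stays well
  under the 2% benign baseline ceiling; tumor defaults are moment-matched
  so medians and quartiles sit near the published per-gene summaries
  (e.g. *GSTP1* median ~40%, IQR ~27-53% in the training-like cohort) and
  values span 0 to ~80%.
* **Inter-gene dependence.** A Gaussian copula with a fixed latent
  correlation matrix (off-diagonals 0.55-0.75) induces the observed
  moderate-to-strong positive inter-gene Pearson correlations
  (empirically ~0.5-0.8 after the marginal transforms) without asserting
  any mechanistic model of coordinated methylation.
* **Clinical covariates.** Gleason group, pathological T group, margins and
  nodes are drawn from the published cohort frequency tables (including the
  "not available" mass, which surfaces as `NA`); PSA is log-normal with the
  published median (38.3 / 19.9 ng/ml).
* **Survival.** Event times are exponential with hazard
  `h0 * exp(lp)`, where `lp` contains the LM+HM-vs-MM indicator derived
  from the first gene at the 15/50 cuts (default log-HR `log(3)`, in the
  range of the published multivariate estimates ~2.7-4.3), a Gleason 8-10
  indicator, a pT3b-4 indicator, and a linear PSA slope. Censoring is
  exponential random censoring plus an administrative horizon; rates
  (0.08/yr with a 13-year horizon; 0.045/yr with a 19-year horizon) are
  assumptions tuned to the reported median follow-ups of ~7 and ~11.5
  years -- the censoring mechanism of the real cohorts is unknown. `h0` is
  calibrated by root-finding on the closed-form expected event fraction
  `mean(lambda_i/(lambda_i + c) * (1 - exp(-(lambda_i + c) H)))` so the
  cohorts hit the published ~20% / ~18% failure rates in expectation.
* **Missingness** is completely at random at small per-gene rates (a few
  markers were unmeasured in a handful of validation-cohort samples).
  The first gene is kept complete because it drives the true risk groups.
* **Reproducibility.** One root seed; each stage (methylation, clinical,
  survival, CV splits) draws from a child stream hashed from the root seed
  and the stage name, so outputs are bit-identical given a seed and
  adding draws to one stage never shifts another.

What the generator does *not* emulate: qPCR fluorescence and calibration
chemistry, intra-tumor spatial heterogeneity, stroma-content variation,
informative censoring, cohort accrual patterns, and treatment effects
(84% vs 21% adjuvant therapy in the real cohorts). Passing calibration
tests therefore show that the estimators behave correctly under the stated
statistical structure -- not that the clinical conclusions transfer to any
particular patient population.

```{r example}
library(methstrat)
cfg <- default_config("PCa1", seed = 1)
cohort <- simulate_cohort(cfg)
head(cohort)
```

## Quantification and diagnostic accuracy

`percent_methylation()` is exact arithmetic; `qc_filter()` accepts a
sample-gene well only when it holds strictly more than 3000 copies after
pre-amplification. The threshold is applied per gene (the protocol's
phrasing leaves per-gene vs per-sample ambiguous; the per-gene reading is
implemented and flagged here). Copy numbers are accepted as non-negative
reals because standard-curve interpolation yields fractional copies.

Diagnostic accuracy uses the empirical ROC only: `roc_auc()` is the
probability a random case exceeds a random control (ties half), computed
from midranks, identical to the trapezoidal area and to the Mann-Whitney
statistic rescaled. A sample is called positive when its value is greater
than *or equal to* the cutoff -- the boundary side is a convention (the
source protocol does not state it), and the tests pin it. Metrics with an
empty denominator are reported missing, never zero. Rank tests use the
tie-corrected normal approximation, adequate at the cohort sizes involved
(42-218); exact enumeration backs the small-sample oracle tests.

## Survival substrate

Kaplan-Meier, log-rank and Cox fitting are delegated to the `survival`
package behind thin module surfaces. Choices that the source analysis
leaves open, fixed here:

* **Ties:** Breslow by default (`tie_method = "efron"` available), matching
  the default of the SAS environment the original analysis used.
* **Intervals:** Wald (`exp(beta +/- 1.96 SE)`), the conventional "HR,
  95% CI" presentation; not profile likelihood.
* **Convergence:** a coefficient walking beyond |beta| > 10, an infinite
  estimate, or a fitter warning marks the fit non-converged;
  `hazard_ratio()` then refuses rather than reporting a meaningless
  interval. This catches monotone-likelihood divergence from perfectly
  separating covariates.
* **Event/censoring ties in time:** the event precedes censoring at the
  same recorded time (standard convention).

The exhaustive cutpoint scans profile thousands of one-covariate Cox
models, so they use a dedicated Newton maximizer of the Breslow partial
likelihood for a single binary covariate (risk-set counts by suffix sums,
step-halving, divergence cap). It is verified against `coxph()` to 1e-6 on
random tied data in the test suite.

## Functional form and the two-stage cutpoint search

`functional_form_scan()` compares a linear Cox trend against (a) linear +
quadratic and (b) a restricted cubic spline, each by likelihood-ratio test;
the verdict is "nonlinear" if either p < 0.05. Because the verdict is a
disjunction of two correlated 0.05-level tests, its familywise false-
nonlinear rate is inherently above 5% (about 6-9% empirically under a
linear generator); the acceptance test band accounts for this. The spline
is the truncated-power restricted (natural) cubic basis -- linear beyond
the boundary knots, `k - 1` columns for `k` knots, nonlinear columns
identically zero at and below the first knot -- with knots at the 10/50/90
percentiles for the default `k = 3`. The knot specification is a stated
default, not an inference about the source analysis.

The cutpoint search is exhaustive and two-staged. Stage 1 considers every
midpoint between consecutive distinct marker values as a dichotomization,
profiles the Breslow partial log-likelihood of the above-cut indicator, and
returns the admissible maximum. Stage 2 fixes the stage-1 cut and considers
every remaining midpoint *on either side* as the second cut; the profiled
model is the LM+HM-vs-MM indicator of the sorted cut pair. (Scanning both
sides matters: when the optimal dichotomization lands high in the marker
range, the only sensible trichotomizations put the second cut below it.)
Admissibility floors -- each group at least 10% of the cohort and at least
5 events -- prevent degenerate minima at the marker extremes; the source
analysis states no floors, so these are package defaults, exposed as
arguments.

Two deliberate reproducibility choices: the selection criterion is the
partial likelihood *alone* (the original selection also weighed clinical
judgment per data set, which cannot be automated; the full profile is
returned so a user can apply judgment), and no multiplicity correction is
applied over candidates -- the selected cutpoint's p-value is optimistically
biased (maximally selected statistic), which is why the cross-validated
comparison below, not the in-sample p-value, carries the evidential weight.

Classification is closed on the moderate interval: LM iff value < cut1,
MM iff cut1 <= value <= cut2, HM iff value > cut2, taken literally from the
published group definitions (< 15%, 15-50%, > 50%).

## Concordance probability and cross-validated comparison

The concordance probability estimate for a proportional-hazards model with
fitted linear predictors `eta`:

    K = 2 / (n(n-1)) * sum_{i<j} 1 / (1 + exp(-|eta_i - eta_j|))

Each pair contributes the model-implied probability that the
higher-predictor subject fails first; tied predictors contribute exactly
0.5. The absolute-difference form bounds the estimate in [0.5, 1], matching
the index's stated range (0.5 no predictive value, 1 perfect). The
estimator uses only the linear predictors -- not the observed events -- so
it is well-defined on arbitrary evaluation records; `model_cpe()` exploits
this for train-fitted / test-evaluated use, scoring *all* test-set pairs
with train coefficients.

`cv_compare()` draws 200 random 80/20 train/test splits (unstratified;
drawn without replacement), re-discovers the methylation categorization on
each training set via the two-stage search, fits both Cox models on the
training set, and scores both on the test set. Reported per model: the mean
test-set CPE and a halfwidth of 1.96 x SD of the 200 measures (the exact
interval construction behind the published "CPE +/- CI" is not printed;
this choice is documented in the output), plus the two-sided paired t-test
on the 200 per-split differences. Splits with too few training events or a
failed fit are resampled and counted; failure on more than 10% of splits
aborts with diagnostics.

One calibration caveat, documented because the test suite exposes it: the
model-based CPE is an optimism-prone index. Adding *any* covariate with a
nonzero estimated coefficient widens the spread of the linear predictor and
therefore raises K on essentially every split, even when the covariate is
pure noise -- the paired t-test will flag a small systematic "improvement"
(about +0.005 to +0.02 CPE at n = 300). The paired comparison is thus
evidence about the *magnitude* of the gain, and a noise covariate is not a
null that this index rejects at the nominal rate. An outcome-based
concordance (Harrell's C on test pairs) would behave differently; it is
out of scope here beyond cross-checks.

## Problem sizes used by the packaged checks

The calibration and recovery checks run at sizes chosen to keep the full
suite comfortably reproducible on a laptop while leaving clear signal
margins: 50 simulated cohorts of n = 500 for the null-CPE average; 10^4
random predictor vectors for the range invariant; 2000 two-arm null
simulations (150 per arm) for log-rank type-I error; 20 benign cohorts of
n = 42 for the baseline ceiling; n = 2000 for multivariate recovery of the
generating log-HR; 20 seeds at n = 1000 for cutpoint recovery (+/- 3 and
+/- 5 points); 20 and 150 seeds at n = 500 for functional-form power and
calibration; and 20 meta-replicates of 50-split cross-validation at
n = 300. The analysis drivers run the published design itself (n = 147,
71, 42; 200 splits).

## Known limitations

* The generator's clinical covariates are drawn independently of each
  other and of methylation; real cohorts have Gleason-stage-PSA
  correlations that the multivariate adjustments would partially absorb.
* Exponential event and censoring times imply constant hazards;
  the published Kaplan-Meier curves suggest this is a simplification.
* Complete-case handling per model matches the published tables'
  variable-wise n, but no imputation is offered.
* The QC threshold is applied per gene; if the protocol intended a
  per-sample total, sensitivity near the threshold would differ.
* `cpe()` is O(n^2) in evaluation records (chunked for memory); adequate
  for cohort sizes here, not for biobank-scale data.
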