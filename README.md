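# methstrat

DNA methylation-guided risk stratification for high-risk prostate cancer,
as a tested, reusable R pipeline.

Promoter hypermethylation of *GSTP1*, *APC*, *RARB*, *PTGS2* and *CCND2*,
measured by quantitative multiplex methylation-specific PCR (QM-MSP) as
percent methylation `100·M/(M+U)`, is highly cancer-specific and — through
a U-shaped relationship with clinical failure — prognostic within the
high-risk group. The package implements the whole analysis chain for
biostatisticians working with such markers:

* **QM-MSP quantification**: percent methylation from methylated (M) and
  unmethylated (U) copy counts, with the strict >3000-copy QC filter
  (`percent_methylation()`, `qc_filter()`, `quantify_plate()`).
* **Diagnostic accuracy**: empirical ROC AUC, sensitivity / specificity /
  PPV / NPV at percent cutoffs, and the standard rank, exact and
  correlation tests (`roc_auc()`, `confusion_at_cutoff()`,
  `mann_whitney()`, `fisher_exact()`, ...).
* **Functional-form exploration**: linear vs quadratic vs restricted cubic
  spline Cox models compared by likelihood-ratio tests
  (`functional_form_scan()`, `spline_basis()`).
* **Two-stage optimal cutpoint discovery**: stage 1 profiles every possible
  dichotomization by Cox partial log-likelihood; stage 2 fixes that cut and
  profiles every trichotomization, yielding the low / moderate / high (LM /
  MM / HM) rule — published cuts 15% / 50% (`dichotomize_search()`,
  `trichotomize_search()`, `classify()`).
* **Prognostic models**: univariate and multivariate Cox models of the
  MM-vs-LM+HM indicator, pathological stage, Gleason score and PSA, with
  Kaplan-Meier / log-rank group comparison (`build_prognostic_models()`,
  `km_estimate()`, `logrank_test()`).
* **Cross-validated model comparison**: the concordance probability
  estimate (CPE)

      K = 2/(n(n−1)) · Σ_{i<j} 1 / (1 + exp(−|η_i − η_j|)),

  an AUC-like index in [0.5, 1] for proportional-hazards models, compared
  between nested models over 200 random 80/20 train/test splits with the
  methylation categorization re-tuned on every training set and a paired
  t-test on the 200 per-split measures (`cpe()`, `model_cpe()`,
  `cv_compare()`).
* **Synthetic cohorts**: a generator (Gaussian copula over zero-inflated
  scaled-Beta marginals, published clinical frequencies, calibrated
  exponential survival with a U-shaped methylation hazard) that makes every
  stage testable without patient data (`default_config()`,
  `simulate_cohort()`).

## Worked example

The numbered drivers under `analysis/` run the full workflow on synthetic
cohorts matching the published design (benign n = 42; training n = 147;
validation n = 71) and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_diagnostic_accuracy.R
Rscript analysis/03_functional_form.R
Rscript analysis/04_cutpoints_and_models.R
Rscript analysis/05_cv_validation.R
```

Output of stage 1 (cohort generation):

```
BPH   n =  42  max per-gene mean methylation = 0.34%
PCa1  n = 147  events = 35 (24%)  median follow-up = 5.6 y  median GSTP1 = 41%
PCa2  n =  71  events = 15 (21%)  median follow-up = 13.7 y  median GSTP1 = 28%
inter-gene Pearson r in the tumor cohort: 0.53-0.73
```

Benign methylation is essentially zero while tumors span 0–80% with
correlated markers — the structure the diagnostic stage exploits (stage 2
reports GSTP1 AUC 0.99 at specificity 1.00). Stage 4 discovers the
cutpoints and builds the prognostic models:

```
two-stage search on the training cohort: cuts 14.9 / 53.8

PCa1 (n = 147): LM/MM/HM = 8/97/42
  log-rank MM vs LM+HM: chi2 = 18.47, p = 0.0000
  GSTP1 trichotomized: MM vs LM+HM (cuts 15/50) uni HR 4.02 (2.02-7.99) p=0.000 | multi HR 4.08 (1.97-8.47) p=0.000
  Gleason score 2-7 vs 8-10                  uni HR 5.77 (2.90-11.50) p=0.000 | multi HR 5.17 (2.59-10.32) p=0.000
```

The exhaustive likelihood profile recovers the generating change points
(truth 15 / 50), and the methylation indicator stays an independent
predictor after adjustment for stage, grade and PSA. Stage 5 quantifies the
added predictive value out of sample:

```
PCa1 (n = 142 complete, 200 splits):
  three clinical variables:          CPE 0.707 +/- 0.047
  three clinical variables + GSTP1:  CPE 0.765 +/- 0.048
  paired t-test on the 200 measures: p = 2.08e-82
```

Adding the trichotomized marker raises the cross-validated concordance of
the clinical model — the package's headline result, mirroring the published
pattern. The methods vignette
(`vignettes/methylation-risk-stratification.Rmd`) documents the model
assumptions, numerical choices, and a calibration caveat of the
model-based CPE.

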