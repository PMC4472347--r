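Package: methstrat
Title: DNA Methylation-Guided Risk Stratification for High-Risk Prostate Cancer
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reusable pipeline for quantitative methylation-specific PCR
    (QM-MSP) based risk stratification of high-risk prostate cancer.
    Computes percent promoter methylation from methylated/unmethylated
    copy counts with copy-number quality control, evaluates benign-versus-
    cancer diagnostic accuracy (empirical ROC, sensitivity/specificity,
    rank and exact association tests), explores the functional form of the
    marker-hazard relationship with quadratic and restricted-cubic-spline
    Cox models, discovers optimal cutpoints by an exhaustive two-stage
    partial-likelihood search (low/moderate/high trichotomization), builds
    univariate and multivariate proportional-hazards models, and compares
    clinico-pathological models with and without the methylation term by
    the concordance probability estimate under repeated random
    sub-sampling cross-validation. A synthetic-cohort generator with a
    Gaussian copula over zero-inflated scaled-Beta marginals makes every
    stage testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
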