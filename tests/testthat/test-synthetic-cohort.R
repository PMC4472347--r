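test_that("configuration invariants are enforced", {
  mp <- data.frame(gene = c("A", "B"), zero_mass = 0.1, shape1 = 1,
                   shape2 = 3, miss_rate = 0)
  freqs <- list(gleason = c("2-6" = 1), pt = c(pT2 = 1),
                margins = c(negative = 1), nodes = c(negative = 1))
  ok <- cohort_config(10, gene_names = c("A", "B"), marginal_params = mp,
                      copula_correlation = equicor(2, 0.5),
                      clinical_freqs = freqs)
  expect_s3_class(ok, "cohort_config")

  # non-positive-definite latent correlation
  bad <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(
    cohort_config(10, gene_names = c("A", "B"), marginal_params = mp,
                  copula_correlation = bad, clinical_freqs = freqs),
    "positive definite")
  # group cuts out of order
  expect_error(
    cohort_config(10, gene_names = c("A", "B"), marginal_params = mp,
                  copula_correlation = equicor(2, 0.5),
                  clinical_freqs = freqs, group_cuts = c(50, 15)),
    "cut1 < cut2")
  # frequencies not summing to one
  freqs_bad <- freqs
  freqs_bad$pt <- c(pT2 = 0.5, pT3a = 0.4)
  expect_error(
    cohort_config(10, gene_names = c("A", "B"), marginal_params = mp,
                  copula_correlation = equicor(2, 0.5),
                  clinical_freqs = freqs_bad),
    "sum to 1")
})

test_that("methylation values stay in range and are seed-deterministic", {
  cfg <- default_config("PCa1", n_patients = 400L, seed = 7)
  m1 <- generate_methylation(cfg)
  m2 <- generate_methylation(cfg)
  expect_identical(m1, m2)
  expect_true(all(is.na(m1) | (m1 >= 0 & m1 <= 100)))
  expect_identical(colnames(m1), cfg$gene_names)

  # empty cohort: a 0-row matrix, no error
  m0 <- generate_methylation(default_config("PCa1", n_patients = 0L))
  expect_identical(dim(m0), c(0L, 5L))

  # full-record determinism across all stages
  co1 <- simulate_cohort(default_config("PCa2", seed = 9))
  co2 <- simulate_cohort(default_config("PCa2", seed = 9))
  expect_identical(co1, co2)
})

test_that("benign defaults give near-zero methylation at every gene", {
  means <- sapply(1:20, function(s) {
    colMeans(generate_methylation(default_config("BPH"), seed = s))
  })
  expect_true(all(means <= 2))
})

test_that("copula induces the configured dependence", {
  # empirical Pearson r at n = 2000 vs the copula-implied value measured by
  # Monte Carlo at n = 1e5 (same marginal transform, independent stream)
  cfg_small <- default_config("PCa1", n_patients = 2000L, seed = 21)
  cfg_big <- default_config("PCa1", n_patients = 100000L, seed = 9090)
  r_small <- cor(generate_methylation(cfg_small), use = "pairwise")
  r_big <- cor(generate_methylation(cfg_big), use = "pairwise")
  expect_lt(max(abs(r_small - r_big)), 0.1)
  # tumors show moderate-to-strong positive inter-gene correlation
  expect_true(all(r_big[upper.tri(r_big)] > 0.4))

  # rank-correlation calibration: without zero inflation the Spearman rho of
  # a Gaussian copula is (6/pi) asin(rho/2)
  mp <- data.frame(gene = c("A", "B"), zero_mass = 0, shape1 = 2,
                   shape2 = 3, miss_rate = 0)
  cfg <- cohort_config(100000L, gene_names = c("A", "B"),
                       marginal_params = mp,
                       copula_correlation = equicor(2, 0.7),
                       clinical_freqs = list(
                         gleason = c("2-6" = 1), pt = c(pT2 = 1),
                         margins = c(negative = 1), nodes = c(negative = 1)),
                       seed = 11)
  m <- generate_methylation(cfg)
  rho_hat <- cor(m[, 1], m[, 2], method = "spearman")
  expect_lt(abs(rho_hat - 6 / pi * asin(0.7 / 2)), 0.02)
})

test_that("clinical covariates follow the configured frequencies", {
  cfg <- default_config("PCa1", n_patients = 10000L, seed = 3)
  cl <- generate_clinical(cfg)
  expect_lt(abs(mean(cl$gleason_group == "2-6") - 0.38), 0.02)
  expect_lt(abs(median(cl$psa) - 38.3) / 38.3, 0.1)
  # missing categories surface as NA, with the configured mass
  expect_lt(abs(mean(is.na(cl$pt_group)) - 9 / 147), 0.01)

  # degenerate point mass
  cfg1 <- default_config("PCa1", n_patients = 50L, seed = 3,
                         clinical_freqs = list(
                           gleason = c("2-6" = 1), pt = c(pT2 = 1),
                           margins = c(negative = 1),
                           nodes = c(negative = 1)))
  expect_true(all(generate_clinical(cfg1)$pt_group == "pT2"))
})

test_that("survival generation hits the target event fraction", {
  co <- simulate_cohort(default_config("PCa1", seed = 3))
  expect_lt(abs(mean(co$cf_event) - 0.20), 0.10)  # n = 147

  co2 <- simulate_cohort(default_config("PCa1", n_patients = 2000L,
                                        seed = 13))
  expect_lt(abs(mean(co2$cf_event) - 0.20), 0.05)  # n >= 1000
  expect_true(all(co2$followup_years > 0))
  expect_true(all(co2$cf_event %in% c(0L, 1L)))
})

test_that("no censoring and zero coefficients give all events", {
  cfg <- default_config("PCa1", n_patients = 60L, seed = 5,
                        log_hazard = c(lmhm = 0, gleason_high = 0,
                                       pt_high = 0, psa = 0),
                        censoring = list(horizon_years = Inf,
                                         rate_per_year = 0),
                        target_event_fraction = NULL,
                        baseline_hazard = 0.05)
  co <- simulate_cohort(cfg)
  expect_true(all(co$cf_event == 1L))
})

test_that("missing first-gene methylation is refused by name", {
  cfg <- default_config("PCa1", n_patients = 5L, seed = 2)
  m <- generate_methylation(cfg)
  rownames(m) <- paste0("P", 1:5)
  m[3, "GSTP1"] <- NA
  cl <- generate_clinical(cfg)
  expect_error(generate_survival(m, cl, cfg), "P3")
})

test_that("a configured log-hazard coefficient is recovered by a Cox fit", {
  # univariate fit on the true group indicator recovers the generating
  # log-HR = log(3) with HR inside [2.5, 3.6] at n = 5000
  cfg <- default_config("PCa1", n_patients = 5000L, seed = 31,
                        log_hazard = c(lmhm = log(3), gleason_high = 0,
                                       pt_high = 0, psa = 0))
  co <- simulate_cohort(cfg)
  co$x <- as.numeric(co$true_group != "MM")
  fit <- cox_fit(co, "x")
  hr <- hazard_ratio(fit, "x")
  expect_gt(hr[["hr"]], 2.5)
  expect_lt(hr[["hr"]], 3.6)
})

test_that("generating coefficients across the range are recovered within 3 SE", {
  set.seed(404)
  betas <- runif(100, -1.5, 1.5)
  ok <- vapply(seq_along(betas), function(i) {
    cfg <- default_config("PCa1", n_patients = 5000L, seed = 500 + i,
                          log_hazard = c(lmhm = betas[i], gleason_high = 0,
                                         pt_high = 0, psa = 0),
                          target_event_fraction = 0.3)
    co <- simulate_cohort(cfg)
    co$x <- as.numeric(co$true_group != "MM")
    fit <- cox_fit(co, "x")
    se <- sqrt(diag(as.matrix(fit$cov)))[1]
    abs(fit$coef[["x"]] - betas[i]) <= 3 * se
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("cohort tables round-trip losslessly through CSV", {
  co <- simulate_cohort(default_config("PCa2", n_patients = 50L, seed = 17))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back, co, tolerance = 0)

  # missing methylation stays missing, not zero
  co$RARB[4] <- NA
  write_cohort(co, path)
  expect_true(is.na(read_cohort(path)$RARB[4]))

  # invariant enforcement with a line number
  bad <- co
  bad$followup_years[2] <- -1
  write_cohort(bad, path)
  expect_error(read_cohort(path), "line 3.*positive")

  # unknown columns are rejected
  odd <- co
  odd$mystery <- 1
  write_cohort(odd, path)
  expect_error(read_cohort(path), "unknown column")
})

test_that("YAML cohort configs are read and unknown keys rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_patients: 12",
    "cohort_label: toy",
    "gene_names: [A, B]",
    "marginal_params:",
    "  - {gene: A, zero_mass: 0.2, shape1: 1.0, shape2: 4.0, miss_rate: 0}",
    "  - {gene: B, zero_mass: 0.2, shape1: 1.0, shape2: 4.0, miss_rate: 0}",
    "copula_correlation:",
    "  - [1.0, 0.5]",
    "  - [0.5, 1.0]",
    "clinical_freqs:",
    "  gleason: {2-6: 1.0}",
    "  pt: {pT2: 1.0}",
    "  margins: {negative: 1.0}",
    "  nodes: {negative: 1.0}",
    "seed: 4"), path)
  cfg <- read_cohort_config(path)
  expect_identical(cfg$n_patients, 12L)
  expect_identical(dim(generate_methylation(cfg)), c(12L, 2L))

  writeLines(c("n_patients: 5", "frobnicate: yes"), path)
  expect_error(read_cohort_config(path), "unknown configuration key")
})
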