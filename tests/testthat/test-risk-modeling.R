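test_that("trichotomy classification honors the published boundaries", {
  rule <- trichotomy_rule(15, 50)
  expect_equal(classify(c(14.9, 15, 50, 50.1, 0, 100), rule),
               c("LM", "MM", "MM", "HM", "LM", "HM"))
  expect_true(is.na(classify(NA_real_, rule)))
  expect_error(trichotomy_rule(50, 15), "cut1 < cut2")
  expect_error(classify(150, rule), "\\[0, 100\\]")

  # monotone: higher methylation never moves back toward LM
  v <- sort(runif(200, 0, 100))
  g <- classify(v, rule)
  ord <- c(LM = 1, MM = 2, HM = 3)[g]
  expect_true(all(diff(ord) >= 0))
})

test_that("the restricted cubic spline basis has its natural-spline structure", {
  set.seed(10)
  x <- runif(200, 0, 80)
  B <- spline_basis(x, n_knots = 3)
  expect_equal(ncol(B), 2L)                  # n_knots - 1 columns
  expect_equal(unname(B[, 1]), x)            # first column is the identity
  knots <- attr(B, "knots")
  expect_equal(knots, unname(quantile(x, c(0.1, 0.5, 0.9))))

  # nonlinear columns vanish at and below the first knot
  low <- x <= knots[1]
  expect_true(all(B[low, -1] == 0))

  # second derivative is zero outside the boundary knots (numerical
  # differentiation oracle on a fine grid)
  grid <- seq(-20, 120, by = 0.05)
  Bg <- spline_basis(grid, knots = knots)
  d2 <- apply(Bg, 2, function(col) diff(col, differences = 2) / 0.05^2)
  outside <- (grid < knots[1] - 0.2)[-c(1, length(grid))] |
    (grid > knots[3] + 0.2)[-c(1, length(grid))]
  expect_lt(max(abs(d2[outside, ])), 1e-6)

  expect_error(spline_basis(rep(c(1, 2), 10), n_knots = 3), "distinct")
})

test_that("functional-form scan refuses degenerate or underpowered input", {
  co <- simulate_cohort(default_config("PCa1", seed = 40))
  expect_error(functional_form_scan(co[1:20, ], "GSTP1"), "underpowered")
  co$flat <- 50
  expect_error(functional_form_scan(co, "flat"), "constant marker")
  sc <- functional_form_scan(co, "GSTP1")
  expect_true(sc$verdict %in% c("linear", "nonlinear"))
  expect_equal(sc$quadratic_vs_linear$df, 1)
  expect_equal(sc$spline_vs_linear$df, 1)   # 3 knots: one nonlinear column
})

test_that("dichotomization scans every admissible midpoint exhaustively", {
  co <- simulate_cohort(default_config("PCa1", n_patients = 300L, seed = 41))
  res <- dichotomize_search(co, "GSTP1")
  prof <- res$profile
  # the reported cut attains the profile maximum among admissible candidates
  expect_equal(res$cut1, prof$cut[which.max(
    ifelse(prof$admissible, prof$loglik, -Inf))])
  expect_true(all(prof$loglik[prof$admissible] <=
                    prof$loglik[prof$cut == res$cut1] + 1e-12))
  # profile bookkeeping: one row per candidate midpoint
  expect_equal(nrow(prof), length(unique(co$GSTP1)) - 1L)

  # with floors relaxed, all n-1 candidates are evaluated
  res0 <- dichotomize_search(co, "GSTP1", min_group_frac = 0,
                             min_events = 0)
  expect_equal(nrow(res0$profile), length(unique(co$GSTP1)) - 1L)

  co$flat <- 1
  expect_error(dichotomize_search(co, "flat"), "constant")
  expect_error(dichotomize_search(co[co$cf_event == 0, ][1:40, ], "GSTP1"),
               "few events")
})

test_that("the dichotomization floors are reported when binding", {
  d <- surv_df(rexp(30), rep(1, 30), m = runif(30, 0, 100))
  expect_error(dichotomize_search(d, "m", min_group_frac = 0.6),
               "no admissible candidate")
})

test_that("a generated step hazard's change point is recovered", {
  cfg <- default_config("PCa1", n_patients = 1000L, seed = 2003,
                        group_cuts = c(30, 99),
                        log_hazard = c(lmhm = log(3), gleason_high = 0,
                                       pt_high = 0, psa = 0),
                        target_event_fraction = 0.30)
  co <- simulate_cohort(cfg)
  res <- dichotomize_search(co, "GSTP1")
  expect_lt(abs(res$cut1 - 30), 3)
})

test_that("trichotomization fixes the first cut and scans the second", {
  cfg <- default_config("PCa1", n_patients = 1000L, seed = 3003,
                        log_hazard = c(lmhm = log(3), gleason_high = 0,
                                       pt_high = 0, psa = 0),
                        target_event_fraction = 0.30)
  co <- simulate_cohort(cfg)
  res <- trichotomize_search(co, "GSTP1", 15)
  expect_equal(res$cut1, 15)
  expect_equal(res$fixed_cut, 15)
  expect_lt(abs(res$cut2 - 50), 5)
  # candidates on both sides of the fixed cut are considered
  expect_true(all(res$profile$cut != 15))
  expect_true(any(res$profile$cut < 15) && any(res$profile$cut > 15))

  expect_error(trichotomize_search(co, "GSTP1", 101), "above all")
  expect_error(trichotomize_search(co, "GSTP1", -1), "below all")

  # only one admissible candidate: it is returned
  d <- surv_df(rexp(60), rbinom(60, 1, 0.8),
               m = rep(c(5, 30, 70), each = 20))
  one <- trichotomize_search(d, "m", 17.5, min_group_frac = 0.3,
                             min_events = 5)
  expect_equal(one$cut2, 50)
})

test_that("prognostic model tables are consistent across modules", {
  co <- simulate_cohort(default_config("PCa1", n_patients = 400L, seed = 44))
  rule <- trichotomy_rule(15, 50)
  mod <- build_prognostic_models(co, rule)
  expect_equal(nrow(mod$table), 4L)

  # univariate HR for the methylation indicator equals the direct Cox fit
  co$lmhm <- as.numeric(classify(co$GSTP1, rule) != "MM")
  direct <- hazard_ratio(cox_fit(co, "lmhm"), "lmhm")
  row <- mod$table[mod$table$variable == "lmhm", ]
  expect_equal(row$uni_hr, direct[["hr"]], tolerance = 1e-10)
  expect_equal(row$uni_p, direct[["p"]], tolerance = 1e-10)

  # records missing pT are dropped from the multivariate fit and counted
  expect_equal(mod$n_dropped_multivariate, sum(is.na(co$pt_group)))
  expect_true(all(mod$table$multi_converged))
})

test_that("null generating coefficients yield HRs near one with covering CIs", {
  cover <- vapply(1:20, function(s) {
    cfg <- default_config("PCa1", n_patients = 250L, seed = 600 + s,
                          log_hazard = c(lmhm = 0, gleason_high = 0,
                                         pt_high = 0, psa = 0))
    co <- simulate_cohort(cfg)
    mod <- build_prognostic_models(co, trichotomy_rule(15, 50))
    row <- mod$table[mod$table$variable == "lmhm", ]
    row$uni_ci_low <= 1 && row$uni_ci_high >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.8)  # ~95% nominal coverage, 20 draws
})
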