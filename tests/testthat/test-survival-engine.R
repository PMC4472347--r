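test_that("Kaplan-Meier follows the product-limit arithmetic", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 2], 1 / 3)

  all_cens <- km_estimate(c(2, 5, 9), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))

  single <- km_estimate(5, 1)
  expect_equal(single$survival, 0)

  # no censoring: KM equals the empirical survival function
  set.seed(2)
  t <- rexp(40)
  km2 <- km_estimate(t, rep(1, 40))
  expect_equal(km2$survival, 1 - ecdf(t)(km2$time))
})

test_that("log-rank behaves on exchangeable, ordered and degenerate groups", {
  t <- c(1, 2, 3, 4, 6, 8)
  e <- c(1, 0, 1, 1, 0, 1)
  same <- logrank_test(rep(t, 2), rep(e, 2), rep(1:2, each = 6))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  # every A event precedes every B event, no censoring
  ord <- logrank_test(c(1, 2, 3, 10, 11, 12), rep(1, 6),
                      rep(c("A", "B"), each = 3))
  expect_gt(ord$statistic, 0)

  three <- logrank_test(rep(t, 3), rep(e, 3), rep(1:3, each = 6))
  expect_equal(three$df, 2)
  expect_equal(three$statistic, 0, tolerance = 1e-12)

  expect_error(logrank_test(t, rep(0, 6), rep(1:2, each = 3)), "no events")
})

test_that("two-group log-rank equals the squared Cox score statistic", {
  set.seed(14)
  for (i in 1:5) {
    d <- surv_df(rexp(60), rbinom(60, 1, 0.7), x = rbinom(60, 1, 0.4))
    lr <- logrank_test(d$followup_years, d$cf_event, d$x)
    fit <- cox_fit(d, "x")
    expect_equal(lr$statistic, fit$score_chisq, tolerance = 1e-6)
  }
})

test_that("Cox fitting matches the brute-force partial-likelihood maximizer", {
  d <- surv_df(c(1, 2, 3, 4), c(1, 1, 1, 1), x = c(1, 0, 1, 0))
  fit <- cox_fit(d, "x")
  b_star <- grid_cox_beta(d$followup_years, d$cf_event, d$x)
  expect_lt(abs(unname(fit$coef) - b_star), 1e-4)
  expect_equal(unname(exp(fit$coef)), unname(hazard_ratio(fit, "x")[["hr"]]))
  # reported log-likelihood equals the definition at the estimate
  expect_equal(fit$loglik,
               brute_breslow_loglik(d$followup_years, d$cf_event, d$x,
                                    unname(fit$coef)),
               tolerance = 1e-8)
})

test_that("Cox fit is equivariant under covariate scaling", {
  set.seed(3)
  d <- surv_df(rexp(80), rbinom(80, 1, 0.6), x = rnorm(80))
  d$x2 <- 2 * d$x
  f1 <- cox_fit(d, "x")
  f2 <- cox_fit(d, "x2")
  expect_equal(unname(f2$coef), unname(f1$coef) / 2, tolerance = 1e-6)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("null covariates give small coefficients and uniform Wald p", {
  set.seed(4)
  ps <- vapply(1:40, function(i) {
    d <- surv_df(rexp(200), rbinom(200, 1, 0.7), x = rnorm(200))
    hazard_ratio(cox_fit(d, "x"), "x")[["p"]]
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.15)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("monotone likelihood is flagged as non-converged", {
  # covariate perfectly orders the event times
  d <- surv_df(1:10, rep(1, 10), x = as.numeric(1:10 > 5))
  fit <- cox_fit(d, "x")
  expect_false(fit$converged)
  expect_error(hazard_ratio(fit, "x"), "converge")
})

test_that("cox_fit validates its inputs", {
  d <- surv_df(c(1, 2), c(1, 0), x = c(1, 2))
  expect_error(cox_fit(d, "nope"), "missing column")
  expect_error(cox_fit(surv_df(c(1, 2), c(0, 0), x = c(1, 2)), "x"),
               "no events")
  expect_error(cox_fit(surv_df(1:5, rep(1, 5), x = rep(2, 5)), "x"),
               "constant covariate")
})

test_that("Wald hazard ratios follow the closed form", {
  hr_ci <- function(b, se) {
    z <- qnorm(0.975)
    c(exp(b), exp(b - z * se), exp(b + z * se))
  }
  expect_equal(round(hr_ci(0, 0.5), 3), c(1.000, 0.375, 2.664))
  expect_equal(hr_ci(log(2), 1e-12)[2:3], c(2, 2), tolerance = 1e-6)
})

test_that("likelihood-ratio test handles self, redundant and strong effects", {
  set.seed(6)
  d <- surv_df(rexp(100), rbinom(100, 1, 0.7), x = rnorm(100))
  f <- cox_fit(d, "x")
  self <- likelihood_ratio_test(f, f)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  d$xc <- d$x  # exact copy: aliased column, no extra df
  f2 <- cox_fit(d, c("x", "xc"))
  red <- likelihood_ratio_test(f, f2)
  expect_lt(abs(red$statistic), 1e-6)

  expect_error(likelihood_ratio_test(cox_fit(d[1:60, ], "x"), f),
               "identical records")

  # power: a strong generated effect is detected at p < 1e-6
  hits <- vapply(1:20, function(i) {
    set.seed(100 + i)
    x <- rnorm(500)
    tt <- rexp(500, exp(x))
    dd <- surv_df(tt, rep(1, 500), x = x, z = rnorm(500))
    null_fit <- cox_fit(dd, "z")
    full_fit <- cox_fit(dd, c("z", "x"))
    likelihood_ratio_test(null_fit, full_fit)$p_value < 1e-6
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the fast binary-covariate profile agrees with the full fitter", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    t <- round(rexp(n), 2)  # rounding forces ties
    e <- rbinom(n, 1, 0.7)
    x <- rbinom(n, 1, 0.4)
    if (sum(e) == 0 || var(x) == 0 ||
          min(sum(e[x == 1]), sum(e[x == 0])) == 0) next
    pr <- methstrat:::.cox_binary_profile(t, e, x)
    if (!pr$converged) next
    fit <- cox_fit(surv_df(t, e, x = x), "x")
    expect_equal(pr$beta, unname(fit$coef), tolerance = 1e-6)
    expect_equal(pr$loglik, fit$loglik, tolerance = 1e-8)
  }
})
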