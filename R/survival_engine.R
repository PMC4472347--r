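#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function; right-continuous,
#' censored subjects leave the risk set after their time.
#'
#' @param time positive follow-up times (years).
#' @param event 0/1 event indicators.
#' @return data.frame with `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             survival = sf$surv)
}

#' Log-rank test
#'
#' Standard observed-minus-expected chi-square over shared event times,
#' `df = k - 1` for `k` groups.
#'
#' @inheritParams km_estimate
#' @param group group membership vector (>= 2 non-empty groups).
#' @return an `assoc_test`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2L) stop("need at least 2 non-empty groups")
  if (sum(event) == 0) stop("undefined test: no events in any group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  new_test_result("log-rank", sd$chisq, df,
                  stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Fit a Cox proportional-hazards model
#'
#' Maximum partial likelihood with Breslow tie handling by default (Efron by
#' flag), on the complete cases of the requested covariate columns.
#' Covariates must be numeric (build indicator columns first, as
#' [build_prognostic_models()] does). Monotone-likelihood divergence -- a
#' coefficient growing without bound -- is detected and reported as
#' non-converged rather than silently returned.
#'
#' @param data data.frame containing time, event and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param tie_method `"breslow"` (default) or `"efron"`.
#' @param time_col,event_col column names of follow-up time and event
#'   indicator.
#' @return object of class `cox_fit` with elements `coef`, `cov` (covariance
#'   of the coefficients), `loglik` (partial log-likelihood at the
#'   estimate), `loglik_null`, `n`, `n_events`, `n_dropped`, `converged`,
#'   `tie_method`, `covariates`, `score_chisq`.
#' @export
cox_fit <- function(data, covariates, tie_method = c("breslow", "efron"),
                    time_col = "followup_years", event_col = "cf_event") {
  tie_method <- match.arg(tie_method)
  stopifnot(is.data.frame(data), length(covariates) >= 1L)
  miss <- setdiff(c(time_col, event_col, covariates), names(data))
  if (length(miss))
    stop("data is missing column(s): ", paste(miss, collapse = ", "))
  d <- data[, c(time_col, event_col, covariates), drop = FALSE]
  cc <- stats::complete.cases(d)
  d <- d[cc, , drop = FALSE]
  if (nrow(d) < 2L) stop("fewer than 2 complete records")
  if (sum(d[[event_col]]) < 1) stop("no events among complete records")
  for (cv in covariates) {
    if (!is.numeric(d[[cv]]))
      stop("covariate '", cv, "' must be numeric")
    if (stats::var(d[[cv]]) == 0)
      stop("constant covariate: ", cv)
  }

  f <- stats::as.formula(paste(
    "survival::Surv(", time_col, ",", event_col, ") ~",
    paste(covariates, collapse = "+")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(f, data = d, ties = tie_method),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  converged <- !warned && all(is.finite(cf)) && all(abs(cf) <= 10)
  structure(
    list(coef = cf, cov = stats::vcov(fit),
         loglik = unname(fit$loglik[2]), loglik_null = unname(fit$loglik[1]),
         n = fit$n, n_events = fit$nevent, n_dropped = sum(!cc),
         converged = converged, tie_method = tie_method,
         covariates = covariates, score_chisq = unname(fit$score),
         time_col = time_col, event_col = event_col),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (%s ties): n = %d, events = %d%s\n", x$tie_method,
              x$n, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  se <- sqrt(diag(as.matrix(x$cov)))
  tab <- data.frame(coef = x$coef, HR = exp(x$coef), se = se)
  print(tab, digits = 4)
  cat("partial log-likelihood:", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' Hazard ratio with Wald confidence interval
#'
#' `HR = exp(beta)`, `CI = exp(beta +/- z_{0.975} * SE)`, two-sided Wald
#' p-value.
#'
#' @param fit a converged [cox_fit()].
#' @param name covariate name.
#' @param level confidence level.
#' @return named numeric `c(hr, ci_low, ci_high, p)`.
#' @export
hazard_ratio <- function(fit, name, level = 0.95) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) stop("fit did not converge; hazard ratio undefined")
  if (!name %in% names(fit$coef)) stop("no covariate named '", name, "'")
  b <- fit$coef[[name]]
  se <- sqrt(diag(as.matrix(fit$cov)))[[which(names(fit$coef) == name)]]
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(hr = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se),
    p = 2 * stats::pnorm(-abs(b / se)))
}

#' Likelihood-ratio test of nested Cox models
#'
#' `statistic = 2 * (loglik_full - loglik_null)`, chi-square with degrees of
#' freedom equal to the difference in (estimable) coefficient counts. Both
#' fits must come from identical records; aliased (NA) coefficients do not
#' count toward the degrees of freedom.
#'
#' @param fit_null,fit_full nested [cox_fit()] objects.
#' @return an `assoc_test`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_full) {
  stopifnot(inherits(fit_null, "cox_fit"), inherits(fit_full, "cox_fit"))
  if (fit_null$n != fit_full$n || fit_null$n_events != fit_full$n_events)
    stop("models must be fitted on identical records")
  stat <- 2 * (fit_full$loglik - fit_null$loglik)
  if (stat < -1e-6)
    stop("nesting violation: full-model log-likelihood below null (",
         format(stat / 2), ")")
  stat <- max(stat, 0)
  df <- sum(!is.na(fit_full$coef)) - sum(!is.na(fit_null$coef))
  if (df < 0) stop("full model has fewer coefficients than null model")
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  new_test_result("likelihood ratio", stat, df, p)
}

# Fast exact maximizer of the Breslow partial likelihood for a single binary
# covariate. Used by the exhaustive cutpoint scans, where thousands of
# one-covariate Cox models must be profiled; verified against coxph() in the
# test suite. Returns beta, the maximized partial log-likelihood, and a
# convergence flag (FALSE under monotone-likelihood divergence).
.cox_binary_profile <- function(time, event, x, tol = 1e-9, max_iter = 40L) {
  ord <- order(time)
  t <- time[ord]; e <- event[ord]; z <- x[ord]
  n <- length(t)
  first <- which(!duplicated(t))
  grp <- rep(seq_along(first), diff(c(first, n + 1L)))
  agg <- rowsum(cbind(e, e * z), grp)        # events, group-1 events per time
  n1_risk <- rev(cumsum(rev(z)))[first]      # group-1 subjects still at risk
  n_risk <- n - first + 1L
  keep <- agg[, 1] > 0
  d <- agg[keep, 1]; n1 <- n1_risk[keep]; n0 <- n_risk[keep] - n1
  s1 <- sum(e * z)
  if (length(d) == 0L)
    return(list(beta = NA_real_, loglik = NA_real_, converged = FALSE))

  ll <- function(b) s1 * b - sum(d * log(n0 + exp(b) * n1))
  b <- 0
  conv <- FALSE
  for (i in seq_len(max_iter)) {
    w <- exp(b) * n1
    den <- n0 + w
    g <- s1 - sum(d * w / den)
    h <- -sum(d * n0 * w / den^2)
    if (abs(g) < tol) { conv <- TRUE; break }
    if (h >= 0) break
    step <- -g / h
    # step-halving on likelihood decrease
    l0 <- ll(b)
    repeat {
      bn <- b + step
      if (ll(bn) >= l0 - 1e-12 || abs(step) < 1e-12) break
      step <- step / 2
    }
    b <- b + step
    if (abs(b) > 15) break  # monotone likelihood: divergence
  }
  list(beta = b, loglik = ll(b), converged = conv && abs(b) <= 10)
}
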