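#' Concordance probability estimate (CPE)
#'
#' Model-based concordance index for proportional-hazards models. Under the
#' Cox model the probability that the subject with the larger linear
#' predictor fails first is `1 / (1 + exp(-|eta_i - eta_j|))`; the estimate
#' averages this over all unordered subject pairs:
#' `K = 2/(n(n-1)) * sum_{i<j} 1/(1 + exp(-|eta_i - eta_j|))`.
#' The absolute-difference form bounds the estimate in \[0.5, 1\]: 0.5 means
#' no predictive value (all pairs tied), 1 perfect separation. The estimator
#' uses only the fitted linear predictors, not the event/censoring
#' indicators.
#'
#' @param linear_predictors numeric vector of fitted linear predictors
#'   (length >= 2).
#' @param chunk_size pairs are accumulated in row blocks of this size to
#'   bound memory on large cohorts.
#' @return object of class `cpe` with `estimate` and `n_pairs`.
#' @export
cpe <- function(linear_predictors, chunk_size = 2000L) {
  eta <- linear_predictors
  if (anyNA(eta)) stop("linear predictors contain NA")
  n <- length(eta)
  if (n < 2L) stop("need at least 2 subjects")
  total <- 0
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    d <- abs(outer(eta[idx], eta, "-"))
    total <- total + sum(stats::plogis(d))
  }
  # the full i,j sum counts each unordered pair twice and the diagonal
  # (plogis(0) = 1/2) n times
  est <- (total - n / 2) / (n * (n - 1))
  structure(list(estimate = est, n_pairs = n * (n - 1) / 2, n = n),
            class = "cpe")
}

#' @export
print.cpe <- function(x, ...) {
  cat(sprintf("CPE = %.4f over %d pairs (n = %d)\n", x$estimate,
              x$n_pairs, x$n))
  invisible(x)
}

#' CPE of a fitted Cox model on (possibly new) records
#'
#' Computes linear predictors `x' beta` with the fit's coefficients on the
#' supplied records -- which may differ from the fitting records, enabling
#' train-fitted / test-evaluated use -- and applies [cpe()]. All pairs of
#' the supplied records are evaluated. Aliased (NA) coefficients contribute
#' zero.
#'
#' @param fit a converged [cox_fit()].
#' @param records data.frame containing the fit's covariate columns.
#' @return a `cpe` object.
#' @export
model_cpe <- function(fit, records) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) stop("fit did not converge")
  miss <- setdiff(fit$covariates, names(records))
  if (length(miss))
    stop("records are missing covariate(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(records[, fit$covariates, drop = FALSE])
  if (anyNA(X))
    stop("missing covariate values in records; supply complete cases")
  b <- fit$coef
  b[is.na(b)] <- 0
  cpe(drop(X %*% b))
}

#' Paired t-test
#'
#' Two-sided paired t-test: `t = mean(d) / (sd(d)/sqrt(n))`, `df = n - 1`,
#' with `d = a - b`. Identically-zero differences give statistic 0 and
#' p = 1 (identical inputs carry no evidence of a difference); a non-zero
#' constant difference gives an infinite statistic and p = 0.
#'
#' @param a,b equal-length numeric vectors (length >= 2).
#' @return an `assoc_test`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch: a and b must pair up")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(new_test_result("paired t", 0, n - 1, 1))
    return(new_test_result("paired t", sign(m) * Inf, n - 1, 0))
  }
  t <- m / (s / sqrt(n))
  new_test_result("paired t", t, n - 1,
                  2 * stats::pt(-abs(t), df = n - 1))
}

#' Model specification for cross-validated comparison
#'
#' @param clinical numeric covariate columns shared by both models (e.g.
#'   `c("pt_high", "gleason_high", "psa")`).
#' @param methylation if `TRUE`, the model adds a trichotomized-methylation
#'   indicator whose cuts are re-discovered on each training set by the
#'   two-stage search.
#' @param marker marker column used when `methylation = TRUE`.
#' @param extra additional fixed numeric covariate columns (e.g. a noise
#'   covariate for calibration experiments).
#' @return object of class `cv_model_spec`.
#' @export
model_spec <- function(clinical, methylation = FALSE, marker = "GSTP1",
                       extra = character(0)) {
  stopifnot(is.character(clinical), is.logical(methylation))
  structure(list(clinical = clinical, methylation = methylation,
                 marker = marker, extra = extra),
            class = "cv_model_spec")
}

# fit one spec on train, evaluate CPE on test; cutpoint retuning happens
# inside, on the training subset only
.fit_and_score <- function(spec, train, test, min_group_frac, min_events,
                           time_col, event_col) {
  covs <- c(spec$clinical, spec$extra)
  if (spec$methylation) {
    rule <- two_stage_cutpoint_search(train, spec$marker,
                                      min_group_frac = min_group_frac,
                                      min_events = min_events,
                                      time_col = time_col,
                                      event_col = event_col)
    train$.lmhm <- as.numeric(classify(train[[spec$marker]], rule) != "MM")
    test$.lmhm <- as.numeric(classify(test[[spec$marker]], rule) != "MM")
    covs <- c(covs, ".lmhm")
  }
  fit <- cox_fit(train, covs, time_col = time_col, event_col = event_col)
  if (!fit$converged) stop("model did not converge on this split")
  model_cpe(fit, test)$estimate
}

#' Repeated random sub-sampling comparison of two Cox models
#'
#' Draws `n_splits` random train/test partitions (default 200 splits at
#' 80/20, drawn without replacement and without stratification). On each
#' split both model specifications are fitted on the training subset -- any
#' methylation categorization is re-tuned on the training subset only, while
#' clinical covariate codings stay fixed -- and scored by the concordance
#' probability estimate over all test-subset pairs using the train-fitted
#' coefficients. Splits on which either model cannot be fitted are resampled
#' and counted; systematic failure (more than 10% of splits) aborts.
#'
#' @param records cohort data.frame; complete cases on all used columns are
#'   taken upfront so both models see identical subjects.
#' @param spec_a,spec_b two [model_spec()]s.
#' @param n_splits number of random splits (>= 2).
#' @param train_frac training fraction in (0, 1).
#' @param seed root seed for the split stream.
#' @param min_group_frac,min_events floors passed to the cutpoint search.
#' @param min_train_events minimum training-subset events for a split to be
#'   attempted.
#' @param time_col,event_col survival column names.
#' @return object of class `cv_comparison`: `per_split` (data.frame of
#'   paired CPE values), `mean_a`, `mean_b`, `halfwidth_a`, `halfwidth_b`
#'   (1.96 x SD over splits), `paired_t`, `n_splits`, `train_frac`, `seed`,
#'   `n_resampled`.
#' @export
cv_compare <- function(records, spec_a, spec_b, n_splits = 200,
                       train_frac = 0.80, seed = 1L,
                       min_group_frac = 0.10, min_events = 5,
                       min_train_events = 5,
                       time_col = "followup_years",
                       event_col = "cf_event") {
  stopifnot(inherits(spec_a, "cv_model_spec"),
            inherits(spec_b, "cv_model_spec"))
  if (n_splits < 2) stop("n_splits must be at least 2")
  stopifnot(train_frac > 0, train_frac < 1)

  used <- unique(c(time_col, event_col, spec_a$clinical, spec_a$extra,
                   spec_b$clinical, spec_b$extra,
                   if (spec_a$methylation) spec_a$marker,
                   if (spec_b$methylation) spec_b$marker))
  miss <- setdiff(used, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  d <- records[stats::complete.cases(records[, used]), , drop = FALSE]
  n <- nrow(d)
  n_train <- floor(train_frac * n)
  if (n_train < 2L || n - n_train < 2L)
    stop("cohort too small for a ", train_frac, " train fraction")

  set.seed(child_seed(seed, "cv"))
  cpe_a <- cpe_b <- numeric(n_splits)
  n_resampled <- 0L
  max_fail <- ceiling(0.10 * n_splits)
  for (s in seq_len(n_splits)) {
    repeat {
      idx <- sample.int(n, n_train)
      train <- d[idx, , drop = FALSE]
      test <- d[-idx, , drop = FALSE]
      if (sum(train[[event_col]]) < min_train_events) {
        n_resampled <- n_resampled + 1L
      } else {
        res <- tryCatch(list(
          a = .fit_and_score(spec_a, train, test, min_group_frac,
                             min_events, time_col, event_col),
          b = .fit_and_score(spec_b, train, test, min_group_frac,
                             min_events, time_col, event_col)),
          error = function(e) e)
        if (!inherits(res, "error")) {
          cpe_a[s] <- res$a; cpe_b[s] <- res$b
          break
        }
        n_resampled <- n_resampled + 1L
      }
      if (n_resampled > max_fail)
        stop("systematic fit failure: more than 10% of splits (",
             n_resampled, ") could not be fitted; last error: ",
             if (exists("res") && inherits(res, "error"))
               conditionMessage(res) else "too few training events")
    }
  }

  structure(
    list(per_split = data.frame(split = seq_len(n_splits), cpe_a = cpe_a,
                                cpe_b = cpe_b),
         mean_a = mean(cpe_a), mean_b = mean(cpe_b),
         halfwidth_a = 1.96 * stats::sd(cpe_a),
         halfwidth_b = 1.96 * stats::sd(cpe_b),
         paired_t = paired_t_test(cpe_b, cpe_a),
         n_splits = as.integer(n_splits), train_frac = train_frac,
         seed = as.integer(seed), n_resampled = n_resampled, n = n),
    class = "cv_comparison")
}

#' @export
print.cv_comparison <- function(x, ...) {
  cat(sprintf("Repeated sub-sampling CV: %d splits at %.0f/%.0f (n = %d)\n",
              x$n_splits, 100 * x$train_frac, 100 * (1 - x$train_frac),
              x$n))
  cat(sprintf("  model A: CPE %.3f +/- %.3f\n", x$mean_a, x$halfwidth_a))
  cat(sprintf("  model B: CPE %.3f +/- %.3f\n", x$mean_b, x$halfwidth_b))
  cat(sprintf("  paired t (B - A): t = %.3f, p = %.4g\n",
              x$paired_t$statistic, x$paired_t$p_value))
  if (x$n_resampled > 0)
    cat("  resampled splits:", x$n_resampled, "\n")
  invisible(x)
}
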