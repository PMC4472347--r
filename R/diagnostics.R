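#' Confusion table at a methylation cutoff
#'
#' Calls a sample positive iff its marker value is greater than or equal to
#' the cutoff. Missing values are excluded and counted.
#'
#' @param case_values marker values in diseased samples.
#' @param control_values marker values in benign samples.
#' @param cutoff positivity threshold (percent); the boundary is positive.
#' @return list of class `confusion` with `TP`, `FP`, `TN`, `FN` and the
#'   numbers of excluded missing values.
#' @export
confusion_at_cutoff <- function(case_values, control_values, cutoff) {
  n_miss_case <- sum(is.na(case_values))
  n_miss_ctrl <- sum(is.na(control_values))
  ca <- case_values[!is.na(case_values)]
  co <- control_values[!is.na(control_values)]
  if (length(ca) == 0L || length(co) == 0L)
    stop("need at least one non-missing case and control value")
  structure(
    list(TP = sum(ca >= cutoff), FN = sum(ca < cutoff),
         TN = sum(co < cutoff), FP = sum(co >= cutoff),
         n_missing_cases = n_miss_case, n_missing_controls = n_miss_ctrl,
         cutoff = cutoff),
    class = "confusion")
}

#' Sensitivity, specificity and predictive values
#'
#' Metrics with an empty denominator are reported as `NA`, never as 0.
#'
#' @param t a `confusion` table (or any list with `TP`, `FP`, `TN`, `FN`).
#' @return named numeric vector `c(sensitivity, specificity, ppv, npv)`.
#' @export
sens_spec_ppv_npv <- function(t) {
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = frac(t$TP, t$TP + t$FN),
    specificity = frac(t$TN, t$TN + t$FP),
    ppv = frac(t$TP, t$TP + t$FP),
    npv = frac(t$TN, t$TN + t$FN))
}

#' Empirical ROC area under the curve
#'
#' The probability that a randomly chosen case exceeds a randomly chosen
#' control, ties counting one half -- equal to the trapezoidal area under
#' the empirical ROC curve. Computed from midranks, which equals the
#' all-pairs mean.
#'
#' @inheritParams confusion_at_cutoff
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(case_values, control_values) {
  ca <- case_values[!is.na(case_values)]
  co <- control_values[!is.na(control_values)]
  n1 <- length(ca); n0 <- length(co)
  if (n1 == 0L || n0 == 0L)
    stop("need at least one non-missing case and control value")
  r <- rank(c(ca, co))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank, exact and correlation tests
#'
#' Thin, uniformly-shaped wrappers around the standard two-sided tests used
#' throughout the analysis: Mann-Whitney U (two groups; midrank ties,
#' tie-corrected normal approximation, no continuity correction),
#' Kruskal-Wallis (more than two groups), Fisher's exact test on a 2x2
#' table, and Pearson / Spearman correlation. Missing values are dropped
#' pairwise.
#'
#' @param x,y numeric vectors.
#' @return an `assoc_test` with `method`, `statistic`, `df`, `p_value` and,
#'   where meaningful, `estimate`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  w <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  new_test_result("Mann-Whitney U", w$statistic, NA_real_, w$p.value)
}

#' @rdname mann_whitney
#' @param groups list of numeric vectors (one per category).
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  stopifnot(all(lengths(groups) >= 1L))
  k <- stats::kruskal.test(groups)
  new_test_result("Kruskal-Wallis", k$statistic, k$parameter, k$p.value)
}

#' @rdname mann_whitney
#' @param table 2x2 matrix of non-negative integer counts.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  f <- stats::fisher.test(table)
  new_test_result("Fisher exact", NA_real_, NA_real_, f$p.value,
                  estimate = f$estimate)
}

#' @rdname mann_whitney
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  new_test_result("Pearson correlation", ct$statistic, ct$parameter,
                  ct$p.value, estimate = ct$estimate)
}

#' @rdname mann_whitney
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  new_test_result("Spearman correlation", ct$statistic, NA_real_,
                  ct$p.value, estimate = ct$estimate)
}

#' Allred immunostaining score
#'
#' Sums a proportion-of-positive-cells score (0-5) and a staining-intensity
#' score (0-3); totals of 0-2 are called negative, 3-8 positive.
#'
#' @param proportion_score integer 0-5.
#' @param intensity_score integer 0-3.
#' @return list with `total` and `call` (`"positive"` / `"negative"`).
#' @export
allred_classify <- function(proportion_score, intensity_score) {
  if (length(proportion_score) != 1L || length(intensity_score) != 1L ||
        proportion_score != round(proportion_score) ||
        intensity_score != round(intensity_score))
    stop("scores must be single integers")
  if (proportion_score < 0 || proportion_score > 5)
    stop("proportion score must be in 0-5")
  if (intensity_score < 0 || intensity_score > 3)
    stop("intensity score must be in 0-3")
  total <- as.integer(proportion_score + intensity_score)
  list(total = total, call = if (total <= 2L) "negative" else "positive")
}

#' Per-gene diagnostic accuracy report
#'
#' For every gene: empirical AUC (cancer vs benign), the Mann-Whitney
#' p-value, and sensitivity/specificity/PPV/NPV at each requested
#' methylation cutoff.
#'
#' @param benign,cancer cohort data.frames containing the gene columns.
#' @param genes gene columns to evaluate.
#' @param cutoffs positivity cutoffs in percent.
#' @return long data.frame, one row per gene x cutoff.
#' @export
diagnostic_summary <- function(benign, cancer,
                               genes = c("GSTP1", "APC", "RARB", "PTGS2",
                                         "CCND2"),
                               cutoffs = c(1, 2)) {
  rows <- list()
  for (g in genes) {
    ca <- cancer[[g]]; co <- benign[[g]]
    auc <- roc_auc(ca, co)
    mw <- mann_whitney(ca, co)
    for (cut in cutoffs) {
      tab <- confusion_at_cutoff(ca, co, cut)
      m <- sens_spec_ppv_npv(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, cutoff = cut, auc = auc, mw_p = mw$p_value,
        sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
        ppv = m[["ppv"]], npv = m[["npv"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
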