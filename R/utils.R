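#' Derive a child RNG seed for a named stage
#'
#' One root seed drives a whole simulation; each stochastic stage draws from
#' its own stream whose seed is a deterministic hash of the root seed and the
#' stage name. Keeps stages decoupled: adding draws to one stage does not
#' shift another stage's stream.
#'
#' @param seed integer root seed.
#' @param stage character stage name, e.g. `"methylation"`.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared container for test results (method, statistic, df, p-value)
new_test_result <- function(method, statistic, df = NA_real_, p_value,
                            estimate = NULL) {
  # guard against p-values a hair outside [0, 1] from floating-point sums
  if (!is.na(p_value)) p_value <- min(max(p_value, 0), 1)
  structure(
    list(method = method, statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), estimate = unname(estimate)),
    class = "assoc_test"
  )
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic, digits = 6),
      if (!is.na(x$df)) paste0("(df = ", format(x$df), ")") else "",
      " p =", format.pval(x$p_value, digits = 4), "\n")
  if (!is.null(x$estimate))
    cat("  estimate  =", format(x$estimate, digits = 6), "\n")
  invisible(x)
}
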