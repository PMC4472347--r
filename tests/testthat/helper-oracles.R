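# Independent oracles and tiny fixture builders used across the suite.

# Breslow partial log-likelihood evaluated directly from its definition:
# sum over event times of (sum of event-subject terms) minus d_t times the
# log of the risk-set sum. Independent of the fitting code paths.
brute_breslow_loglik <- function(time, event, x, beta) {
  ut <- sort(unique(time[event == 1]))
  vapply(beta, function(b) {
    ll <- sum(x[event == 1] * b)
    for (u in ut) {
      d <- sum(event == 1 & time == u)
      ll <- ll - d * log(sum(exp(x[time >= u] * b)))
    }
    ll
  }, numeric(1))
}

# grid-search maximizer of the Breslow partial likelihood (1-D)
grid_cox_beta <- function(time, event, x, lo = -10, hi = 10, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  grid[which.max(brute_breslow_loglik(time, event, x, grid))]
}

# O(n^2) double-loop concordance probability estimate
brute_cpe <- function(eta) {
  n <- length(eta)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + 1 / (1 + exp(-abs(eta[i] - eta[j])))
    }
  }
  s / (n * (n - 1) / 2)
}

# exhaustive all-pairs AUC with half-credit ties
brute_auc <- function(cases, controls) {
  s <- 0
  for (a in cases) for (b in controls)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(cases) * length(controls))
}

# two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins (same relative tolerance convention as
# the standard implementation)
brute_fisher_p <- function(a, r1, r2, c1) {
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(ks, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# minimal survival data.frame in cohort column conventions
surv_df <- function(time, event, ...) {
  data.frame(followup_years = time, cf_event = event, ...)
}

# small correlation matrix helper
equicor <- function(p, rho) {
  R <- matrix(rho, p, p)
  diag(R) <- 1
  R
}
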