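#' Generate correlated percent-methylation values
#'
#' Draws an `n_patients x n_genes` matrix of percent methylation. Latent
#' dependence is induced by a Gaussian copula with the configured correlation
#' matrix; each gene's marginal is a zero-inflated scaled-Beta mixture (point
#' mass at 0 percent plus `100 * Beta(shape1, shape2)`), so all values lie in
#' \[0, 100\]. Per-gene completely-at-random missingness is applied last.
#' Deterministic given `seed`.
#'
#' @param config a [cohort_config()].
#' @param seed root seed (defaults to `config$seed`); the methylation stream
#'   uses `child_seed(seed, "methylation")`.
#' @return numeric matrix with one column per gene, `NA` for missing.
#' @export
generate_methylation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  genes <- config$gene_names
  ng <- length(genes)
  if (n == 0L)
    return(matrix(numeric(0), nrow = 0, ncol = ng,
                  dimnames = list(NULL, genes)))

  set.seed(child_seed(seed, "methylation"))
  Z <- matrix(stats::rnorm(n * ng), n, ng) %*% config$chol_R
  U <- stats::pnorm(Z)

  mp <- config$marginal_params
  M <- matrix(NA_real_, n, ng, dimnames = list(NULL, genes))
  for (j in seq_len(ng)) {
    p0 <- mp$zero_mass[j]
    u <- U[, j]
    v <- numeric(n)
    pos <- u >= p0
    if (p0 < 1 && any(pos))
      v[pos] <- 100 * stats::qbeta((u[pos] - p0) / (1 - p0),
                                   mp$shape1[j], mp$shape2[j])
    M[, j] <- v
  }
  for (j in seq_len(ng)) {
    r <- mp$miss_rate[j]
    if (r > 0) M[stats::runif(n) < r, j] <- NA_real_
  }
  M
}

#' Generate clinical covariates
#'
#' Draws Gleason group, pathological T group, margin and node status from the
#' configured category frequencies (a `"missing"` category yields `NA`) and
#' preoperative PSA from the configured log-normal. Deterministic given
#' `seed`.
#'
#' @inheritParams generate_methylation
#' @return data.frame with columns `psa`, `gleason_group`, `pt_group`,
#'   `margins`, `nodes`.
#' @export
generate_clinical <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  set.seed(child_seed(seed, "clinical"))

  draw <- function(freqs) {
    out <- if (n == 0L) character(0) else
      sample(names(freqs), n, replace = TRUE, prob = freqs)
    out[out == "missing"] <- NA_character_
    out
  }
  psa <- stats::rlnorm(n, config$psa_params[["meanlog"]],
                       config$psa_params[["sdlog"]])
  data.frame(
    psa = psa,
    gleason_group = draw(config$clinical_freqs$gleason),
    pt_group = draw(config$clinical_freqs$pt),
    margins = draw(config$clinical_freqs$margins),
    nodes = draw(config$clinical_freqs$nodes),
    stringsAsFactors = FALSE
  )
}

# linear predictor of the generating hazard model; missing pT contributes the
# reference level (0) at generation time
.generating_lp <- function(methylation, clinical, config) {
  g1 <- methylation[, config$gene_names[1]]
  rule <- trichotomy_rule(config$group_cuts[1], config$group_cuts[2])
  tg <- classify(g1, rule)
  b <- config$log_hazard
  lp <- numeric(length(g1))
  if ("lmhm" %in% names(b))
    lp <- lp + b[["lmhm"]] * as.numeric(tg != "MM")
  if ("meth_linear" %in% names(b))
    lp <- lp + b[["meth_linear"]] * g1
  if ("gleason_high" %in% names(b))
    lp <- lp + b[["gleason_high"]] *
      as.numeric(!is.na(clinical$gleason_group) &
                   clinical$gleason_group == "8-10")
  if ("pt_high" %in% names(b))
    lp <- lp + b[["pt_high"]] *
      as.numeric(!is.na(clinical$pt_group) &
                   clinical$pt_group %in% c("pT3b", "pT4"))
  if ("psa" %in% names(b))
    lp <- lp + b[["psa"]] * clinical$psa
  list(lp = lp, true_group = tg)
}

#' Generate follow-up times and clinical-failure indicators
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(linear predictor)` over the configured covariates,
#' including the low-or-high-vs-moderate methylation indicator derived from
#' the first gene via `group_cuts`. Censoring is exponential random censoring
#' plus an administrative horizon; an event is recorded iff the event time
#' precedes both. When `target_event_fraction` is set, the baseline hazard is
#' first calibrated by root-finding on the closed-form expected event
#' fraction `mean(lambda_i/(lambda_i+c) * (1 - exp(-(lambda_i+c)*H)))`.
#'
#' @param methylation matrix from [generate_methylation()]; the first gene
#'   must be non-missing for every patient.
#' @param clinical data.frame from [generate_clinical()].
#' @param config a [cohort_config()].
#' @param seed root seed; the survival stream uses
#'   `child_seed(seed, "survival")`.
#' @return data.frame with `followup_years`, `cf_event`, `true_group`.
#' @export
generate_survival <- function(methylation, clinical, config,
                              seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(methylation)
  stopifnot(nrow(clinical) == n)
  g1 <- methylation[, config$gene_names[1]]
  if (anyNA(g1)) {
    ids <- rownames(methylation) %||% as.character(seq_len(n))
    stop("missing ", config$gene_names[1], " methylation for patient(s): ",
         paste(ids[is.na(g1)], collapse = ", "))
  }
  if (n == 0L)
    return(data.frame(followup_years = numeric(0), cf_event = integer(0),
                      true_group = character(0)))

  gl <- .generating_lp(methylation, clinical, config)
  H <- config$censoring$horizon_years
  cr <- config$censoring$rate_per_year

  h0 <- config$baseline_hazard
  if (!is.null(config$target_event_fraction)) {
    target <- config$target_event_fraction
    efrac <- function(log_h0) {
      lam <- exp(log_h0 + gl$lp)
      tot <- lam + cr
      p <- lam / tot * (if (is.finite(H)) 1 - exp(-tot * H) else 1)
      mean(p) - target
    }
    sol <- stats::uniroot(efrac, lower = log(1e-8), upper = log(50),
                          tol = 1e-10)
    h0 <- exp(sol$root)
  }

  set.seed(child_seed(seed, "survival"))
  lam <- h0 * exp(gl$lp)
  t_event <- stats::rexp(n, lam)
  t_cens <- if (cr > 0) stats::rexp(n, cr) else rep(Inf, n)
  obs <- pmin(t_event, t_cens, H)
  # tie convention: an event occurring exactly at the censoring time counts
  data.frame(
    followup_years = obs,
    cf_event = as.integer(t_event <= pmin(t_cens, H)),
    true_group = gl$true_group,
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete cohort
#'
#' Runs [generate_methylation()], [generate_clinical()] and
#' [generate_survival()] under per-stage child seeds of one root seed and
#' assembles patient records.
#'
#' @inheritParams generate_methylation
#' @return data.frame with columns `patient_id`, one column per gene (percent
#'   methylation), `psa`, `gleason_group`, `pt_group`, `margins`, `nodes`,
#'   `followup_years`, `cf_event`, `true_group`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  M <- generate_methylation(config, seed)
  ids <- if (config$n_patients > 0)
    sprintf("%s_%04d", gsub("[^A-Za-z0-9]", "", config$cohort_label),
            seq_len(config$n_patients)) else character(0)
  rownames(M) <- ids
  cl <- generate_clinical(config, seed)
  sv <- generate_survival(M, cl, config, seed)
  out <- data.frame(patient_id = ids, M, cl, sv,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

.cohort_columns <- function(genes) {
  c("patient_id", genes, "psa", "gleason_group", "pt_group", "margins",
    "nodes", "followup_years", "cf_event", "true_group")
}

#' Write / read a cohort table
#'
#' Comma-separated UTF-8 text with a header row of the patient-record field
#' names, missing token `"NA"`, and numeric values at full (17 significant
#' digit) precision so a write/read round trip is lossless.
#'
#' @param records cohort data.frame as from [simulate_cohort()].
#' @param path output file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   validated records.
#' @export
write_cohort <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x)
    ifelse(is.na(x), NA_character_, formatC(x, digits = 17, format = "g")))
  utils::write.csv(out, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param genes gene columns expected in the file.
#' @export
read_cohort <- function(path,
                        genes = c("GSTP1", "APC", "RARB", "PTGS2", "CCND2")) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  d <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA"),
    error = function(e) stop("malformed cohort file: ", conditionMessage(e)))
  want <- .cohort_columns(genes)
  core <- setdiff(want, "true_group")
  miss <- setdiff(core, names(d))
  if (length(miss))
    stop("cohort file is missing column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(d), want)
  if (length(extra))
    stop("cohort file has unknown column(s): ", paste(extra, collapse = ", "))

  for (g in genes) {
    bad <- which(!is.na(d[[g]]) & (d[[g]] < 0 | d[[g]] > 100))
    if (length(bad))
      stop("line ", bad[1] + 1L, ": methylation value for ", g,
           " outside [0, 100]")
  }
  bad <- which(is.na(d$followup_years) | d$followup_years <= 0)
  if (length(bad))
    stop("line ", bad[1] + 1L, ": followup_years must be positive")
  bad <- which(!d$cf_event %in% c(0L, 1L))
  if (length(bad))
    stop("line ", bad[1] + 1L, ": cf_event must be 0 or 1")
  d
}
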