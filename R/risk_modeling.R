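#' Methylation trichotomy rule
#'
#' Two percent cutoffs defining low (LM, value < cut1), moderate
#' (MM, cut1 <= value <= cut2) and high (HM, value > cut2) methylation
#' groups. The published rule for the first marker gene is 15/50.
#'
#' @param cut1,cut2 percents with `0 < cut1 < cut2 < 100`.
#' @return object of class `trichotomy_rule`.
#' @export
trichotomy_rule <- function(cut1, cut2) {
  stopifnot(length(cut1) == 1L, length(cut2) == 1L)
  if (!(cut1 > 0 && cut1 < cut2 && cut2 < 100))
    stop("cuts must satisfy 0 < cut1 < cut2 < 100")
  structure(list(cut1 = cut1, cut2 = cut2, labels = c("LM", "MM", "HM")),
            class = "trichotomy_rule")
}

#' Classify methylation values into LM/MM/HM
#'
#' The moderate group is closed at both ends: LM iff `value < cut1`, MM iff
#' `cut1 <= value <= cut2`, HM iff `value > cut2`. Missing values propagate
#' to missing groups.
#'
#' @param value percent methylation values in \[0, 100\] (NA allowed).
#' @param rule a [trichotomy_rule()].
#' @return character vector of `"LM"`, `"MM"`, `"HM"` (or `NA`).
#' @export
classify <- function(value, rule) {
  stopifnot(inherits(rule, "trichotomy_rule"))
  if (any(!is.na(value) & (value < 0 | value > 100)))
    stop("methylation values must lie in [0, 100]")
  out <- rep(NA_character_, length(value))
  out[!is.na(value) & value < rule$cut1] <- "LM"
  out[!is.na(value) & value >= rule$cut1 & value <= rule$cut2] <- "MM"
  out[!is.na(value) & value > rule$cut2] <- "HM"
  out
}

#' Restricted cubic spline basis
#'
#' Truncated-power natural (restricted) cubic spline basis: linear beyond
#' the boundary knots, `n_knots - 1` columns, the first being the identity.
#' Knots sit at marker quantiles (10/50/90 percentiles for 3 knots, the
#' usual placements for 4-5). The nonlinear columns are identically zero at
#' and below the first knot.
#'
#' @param x numeric vector (>= `n_knots` distinct values).
#' @param n_knots number of knots (3-5 use standard quantile placements).
#' @param knots optional explicit knot locations (overrides `n_knots`).
#' @return matrix with `n_knots - 1` columns, attribute `"knots"`.
#' @export
spline_basis <- function(x, n_knots = 3, knots = NULL) {
  if (is.null(knots)) {
    probs <- switch(as.character(n_knots),
      "3" = c(0.10, 0.50, 0.90),
      "4" = c(0.05, 0.35, 0.65, 0.95),
      "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
      seq(0.05, 0.95, length.out = n_knots))
    if (length(unique(x[!is.na(x)])) < n_knots)
      stop("need at least ", n_knots, " distinct values for ", n_knots,
           " knots")
    knots <- unname(stats::quantile(x, probs, na.rm = TRUE, type = 7))
  }
  knots <- sort(knots)
  K <- length(knots)
  if (K < 3L) stop("need at least 3 knots")
  if (anyDuplicated(knots)) stop("knots must be distinct")

  tK <- knots[K]; tK1 <- knots[K - 1L]
  norm <- (tK - knots[1])^2
  p3 <- function(u) pmax(u, 0)^3
  cols <- lapply(seq_len(K - 2L), function(j) {
    tj <- knots[j]
    (p3(x - tj) -
       p3(x - tK1) * (tK - tj) / (tK - tK1) +
       p3(x - tK) * (tK1 - tj) / (tK - tK1)) / norm
  })
  B <- cbind(x, do.call(cbind, cols))
  colnames(B) <- paste0("rcs", seq_len(K - 1L))
  attr(B, "knots") <- knots
  B
}

#' Explore the functional form of the marker-hazard relationship
#'
#' Fits Cox models with (a) a linear marker term, (b) linear plus quadratic,
#' and (c) a restricted-cubic-spline basis, and compares (b) and (c) to (a)
#' with likelihood-ratio tests. The verdict is `"nonlinear"` iff either test
#' has p below `alpha`. Underpowered inputs are refused, not silently fit.
#'
#' @param records data.frame with follow-up, event and the marker column.
#' @param marker marker column name.
#' @param min_n,min_events minimum complete records and events required.
#' @param n_knots spline knot count (see [spline_basis()]).
#' @param alpha significance level for the verdict.
#' @param time_col,event_col survival column names.
#' @return list with `verdict`, `quadratic_vs_linear` and
#'   `spline_vs_linear` (`assoc_test`s), the three fits, and `n`/`n_events`.
#' @export
functional_form_scan <- function(records, marker, min_n = 30,
                                 min_events = 10, n_knots = 3, alpha = 0.05,
                                 time_col = "followup_years",
                                 event_col = "cf_event") {
  stopifnot(marker %in% names(records))
  d <- records[stats::complete.cases(
    records[, c(time_col, event_col, marker)]), , drop = FALSE]
  n <- nrow(d)
  ev <- sum(d[[event_col]])
  if (n < min_n || ev < min_events)
    stop("underpowered input: ", n, " complete records with ", ev,
         " events (need >= ", min_n, " and >= ", min_events, ")")
  x <- d[[marker]]
  if (stats::var(x) == 0) stop("constant marker: ", marker)

  dd <- data.frame(d[, c(time_col, event_col)], x = x, x2 = x^2)
  B <- spline_basis(x, n_knots = n_knots)
  sp_cols <- colnames(B)[-1]
  dd[colnames(B)] <- as.data.frame(unclass(B))

  fit_lin <- cox_fit(dd, "x", time_col = time_col, event_col = event_col)
  fit_quad <- cox_fit(dd, c("x", "x2"), time_col = time_col,
                      event_col = event_col)
  fit_sp <- cox_fit(dd, c("rcs1", sp_cols), time_col = time_col,
                    event_col = event_col)
  lrt_quad <- likelihood_ratio_test(fit_lin, fit_quad)
  lrt_sp <- likelihood_ratio_test(fit_lin, fit_sp)
  verdict <- if (lrt_quad$p_value < alpha || lrt_sp$p_value < alpha)
    "nonlinear" else "linear"
  list(verdict = verdict, quadratic_vs_linear = lrt_quad,
       spline_vs_linear = lrt_sp, fit_linear = fit_lin,
       fit_quadratic = fit_quad, fit_spline = fit_sp,
       n = n, n_events = ev, knots = attr(B, "knots"))
}

# shared scaffolding of the two cutpoint scans
.cut_candidates <- function(v) {
  sv <- sort(unique(v))
  if (length(sv) < 2L) return(numeric(0))
  (sv[-length(sv)] + sv[-1]) / 2
}

.scan_profile <- function(time, event, v, indicator_fun, cuts, min_n,
                          min_events) {
  rows <- lapply(cuts, function(cut) {
    x <- indicator_fun(v, cut)
    n1 <- sum(x); n0 <- length(x) - n1
    e1 <- sum(event[x == 1]); e0 <- sum(event) - e1
    adm <- min(n1, n0) >= min_n && min(e1, e0) >= min_events
    ll <- NA_real_
    if (adm) {
      pr <- .cox_binary_profile(time, event, x)
      ll <- pr$loglik
      adm <- adm && pr$converged
    }
    data.frame(cut = cut, loglik = ll, n_low = n0, n_high = n1,
               events_low = e0, events_high = e1, admissible = adm)
  })
  do.call(rbind, rows)
}

#' Exhaustive optimal dichotomization of a marker
#'
#' Considers every possible dichotomization: candidate cuts are midpoints
#' between consecutive sorted distinct marker values. For each admissible
#' candidate (both sides meeting the size and event floors) a univariate Cox
#' model on the above-cut indicator is profiled and its Breslow partial
#' log-likelihood recorded; the returned cut attains the maximum, and the
#' full profile is exposed so clinical judgment can be applied to near-ties.
#' No multiplicity correction is applied over candidates: the selected
#' cutpoint's p-value is optimistically biased (maximally selected
#' statistic) and should be interpreted through out-of-sample validation.
#'
#' @param records data.frame with survival columns and the marker.
#' @param marker marker column name.
#' @param min_group_frac minimum fraction of the cohort on each side.
#' @param min_events minimum events on each side.
#' @param time_col,event_col survival column names.
#' @return object of class `cutpoint_result` with `cut1`, `profile`,
#'   `constraints_used`.
#' @export
dichotomize_search <- function(records, marker, min_group_frac = 0.10,
                               min_events = 5,
                               time_col = "followup_years",
                               event_col = "cf_event") {
  stopifnot(marker %in% names(records))
  d <- records[stats::complete.cases(
    records[, c(time_col, event_col, marker)]), , drop = FALSE]
  v <- d[[marker]]
  if (length(v) == 0L || stats::var(v) == 0)
    stop("constant marker: ", marker)
  ev <- sum(d[[event_col]])
  if (ev < 2 * min_events)
    stop("too few events (", ev, ") for floors of ", min_events,
         " per side")
  cuts <- .cut_candidates(v)
  min_n <- ceiling(min_group_frac * nrow(d))
  prof <- .scan_profile(d[[time_col]], d[[event_col]], v,
                        function(v, cut) as.numeric(v > cut), cuts,
                        min_n, min_events)
  if (!any(prof$admissible))
    stop("no admissible candidate: every dichotomization violates the ",
         "size floor (>= ", min_n, " per side) or event floor (>= ",
         min_events, " per side)")
  best <- which.max(ifelse(prof$admissible, prof$loglik, -Inf))
  structure(
    list(cut1 = prof$cut[best], cut2 = NULL, profile = prof,
         constraints_used = list(min_group_size = min_n,
                                 min_events = min_events),
         marker = marker, n = nrow(d), n_events = ev),
    class = "cutpoint_result")
}

#' Optimal trichotomization with the first cut fixed
#'
#' Fixes one cut and considers all possible trichotomizations: candidate
#' second cuts are every midpoint between consecutive distinct marker values
#' other than the fixed cut, on either side of it (the fixed cut may end up
#' as the lower or the upper boundary of the moderate group). For each
#' candidate the profiled model is the univariate Cox fit on the
#' LM+HM-vs-MM indicator induced by the sorted cut pair; floors apply to the
#' two indicator groups.
#'
#' @inheritParams dichotomize_search
#' @param fixed_cut1 the fixed cut in percent (must lie strictly inside the
#'   observed marker range).
#' @return object of class `cutpoint_result` with `cut1 < cut2` (the sorted
#'   pair), `fixed_cut` (the stage-1 cut), and the full `profile`.
#' @export
trichotomize_search <- function(records, marker, fixed_cut1,
                                min_group_frac = 0.10, min_events = 5,
                                time_col = "followup_years",
                                event_col = "cf_event") {
  stopifnot(marker %in% names(records))
  d <- records[stats::complete.cases(
    records[, c(time_col, event_col, marker)]), , drop = FALSE]
  v <- d[[marker]]
  if (length(v) == 0L || stats::var(v) == 0)
    stop("constant marker: ", marker)
  if (fixed_cut1 >= max(v))
    stop("fixed_cut1 (", fixed_cut1, ") is at or above all marker values")
  if (fixed_cut1 <= min(v))
    stop("fixed_cut1 (", fixed_cut1, ") is at or below all marker values")
  cuts <- .cut_candidates(v)
  cuts <- cuts[cuts != fixed_cut1]
  if (length(cuts) == 0L)
    stop("no candidate second cut distinct from fixed_cut1")
  min_n <- ceiling(min_group_frac * nrow(d))
  ind <- function(v, cut) {
    lo <- min(fixed_cut1, cut); hi <- max(fixed_cut1, cut)
    as.numeric(v < lo | v > hi)  # LM + HM
  }
  prof <- .scan_profile(d[[time_col]], d[[event_col]], v, ind, cuts,
                        min_n, min_events)
  if (!any(prof$admissible))
    stop("no admissible candidate: every trichotomization violates the ",
         "size floor (>= ", min_n, ") or event floor (>= ", min_events,
         ") for the MM vs LM+HM groups")
  best <- which.max(ifelse(prof$admissible, prof$loglik, -Inf))
  structure(
    list(cut1 = min(fixed_cut1, prof$cut[best]),
         cut2 = max(fixed_cut1, prof$cut[best]),
         fixed_cut = fixed_cut1, profile = prof,
         constraints_used = list(min_group_size = min_n,
                                 min_events = min_events),
         marker = marker, n = nrow(d), n_events = sum(d[[event_col]])),
    class = "cutpoint_result")
}

#' Two-stage cutpoint search
#'
#' The first cut is found over all dichotomizations, the second over all
#' trichotomizations with the first fixed -- the selection criterion is the
#' Cox partial log-likelihood throughout.
#'
#' @inheritParams dichotomize_search
#' @return a [trichotomy_rule()] with the discovered cuts; the two
#'   `cutpoint_result`s are attached as attributes `stage1`, `stage2`.
#' @export
two_stage_cutpoint_search <- function(records, marker,
                                      min_group_frac = 0.10, min_events = 5,
                                      time_col = "followup_years",
                                      event_col = "cf_event") {
  s1 <- dichotomize_search(records, marker, min_group_frac, min_events,
                           time_col, event_col)
  s2 <- trichotomize_search(records, marker, s1$cut1, min_group_frac,
                            min_events, time_col, event_col)
  rule <- trichotomy_rule(s2$cut1, s2$cut2)
  attr(rule, "stage1") <- s1
  attr(rule, "stage2") <- s2
  rule
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat("Optimal cutpoint search on", x$marker,
      sprintf("(n = %d, events = %d)\n", x$n, x$n_events))
  if (is.null(x$cut2))
    cat("  cut1 =", format(x$cut1, digits = 4), "\n")
  else
    cat("  cut1 =", format(x$cut1, digits = 4),
        " cut2 =", format(x$cut2, digits = 4), "\n")
  cat("  candidates:", nrow(x$profile), "(",
      sum(x$profile$admissible), "admissible; floors:",
      x$constraints_used$min_group_size, "per group,",
      x$constraints_used$min_events, "events per group)\n")
  invisible(x)
}

# indicator columns used by the prognostic models; NA propagates
.model_covariates <- function(records, rule, marker) {
  grp <- classify(records[[marker]], rule)
  data.frame(
    lmhm = as.numeric(grp != "MM"),
    pt_high = ifelse(is.na(records$pt_group), NA_real_,
                     as.numeric(records$pt_group %in% c("pT3b", "pT4"))),
    gleason_high = ifelse(is.na(records$gleason_group), NA_real_,
                          as.numeric(records$gleason_group == "8-10")),
    psa = records$psa)
}

#' Univariate and multivariate prognostic models
#'
#' Builds the standard clinico-pathological risk table: a univariate Cox
#' model per variable and one multivariate Cox model containing the
#' LM+HM-vs-MM methylation indicator, pathological stage (pT3b-4 vs
#' pT2-3a), Gleason score (8-10 vs 2-7) and continuous preoperative PSA.
#' Records with missing covariates are dropped per model (complete-case)
#' and counted. A non-converged model yields a flagged row, never a silent
#' omission.
#'
#' @param records cohort data.frame.
#' @param rule a [trichotomy_rule()] for the marker.
#' @param marker marker gene column (default first gene, `"GSTP1"`).
#' @param time_col,event_col survival column names.
#' @return list with `table` (one row per variable: univariate and
#'   multivariate HR, 95% CI, p, convergence flags), `uni_fits`,
#'   `multi_fit`, and `n_dropped_multivariate`.
#' @export
build_prognostic_models <- function(records, rule, marker = "GSTP1",
                                time_col = "followup_years",
                                event_col = "cf_event") {
  stopifnot(inherits(rule, "trichotomy_rule"), marker %in% names(records))
  covs <- .model_covariates(records, rule, marker)
  d <- data.frame(records[, c(time_col, event_col)], covs)

  contrasts <- c(
    lmhm = sprintf("%s trichotomized: MM vs LM+HM (cuts %.4g/%.4g)",
                   marker, rule$cut1, rule$cut2),
    pt_high = "Pathological T stage 2-3a vs 3b-4",
    gleason_high = "Gleason score 2-7 vs 8-10",
    psa = "Preoperative PSA continuous")
  vars <- names(contrasts)

  uni_fits <- list()
  rows <- list()
  for (v in vars) {
    fit <- tryCatch(cox_fit(d, v, time_col = time_col,
                            event_col = event_col),
                    error = function(e) NULL)
    uni_fits[[v]] <- fit
    ok <- !is.null(fit) && fit$converged
    hr <- if (ok) hazard_ratio(fit, v) else
      c(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_)
    rows[[v]] <- data.frame(
      variable = v, contrast = contrasts[[v]],
      uni_hr = hr[["hr"]], uni_ci_low = hr[["ci_low"]],
      uni_ci_high = hr[["ci_high"]], uni_p = hr[["p"]],
      uni_converged = ok, stringsAsFactors = FALSE)
  }

  multi_fit <- tryCatch(cox_fit(d, vars, time_col = time_col,
                                event_col = event_col),
                        error = function(e) NULL)
  mok <- !is.null(multi_fit) && multi_fit$converged
  for (v in vars) {
    hr <- if (mok) hazard_ratio(multi_fit, v) else
      c(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_)
    rows[[v]]$multi_hr <- hr[["hr"]]
    rows[[v]]$multi_ci_low <- hr[["ci_low"]]
    rows[[v]]$multi_ci_high <- hr[["ci_high"]]
    rows[[v]]$multi_p <- hr[["p"]]
    rows[[v]]$multi_converged <- mok
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, uni_fits = uni_fits, multi_fit = multi_fit,
       n_dropped_multivariate = if (!is.null(multi_fit))
         multi_fit$n_dropped else sum(!stats::complete.cases(d)))
}
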