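#' Pipeline run configuration
#'
#' Collects input paths, stage toggles and all stage parameters for
#' [run_pipeline()]. Stages: `simulate` (synthetic cohorts), `quantify`
#' (QM-MSP plate export), `diagnose` (benign-vs-cancer accuracy),
#' `functional_form`, `cutpoints`, `models` (prognostic tables + KM/log-rank)
#' and `validate` (cross-validated CPE comparison).
#'
#' @param output_dir directory for report tables (created if absent).
#' @param seed mandatory root seed for all stochastic stages.
#' @param stages character vector of stages to run, in pipeline order.
#' @param cancer_config,benign_config [cohort_config()]s used by the
#'   `simulate` stage.
#' @param cohort_path,benign_path cohort CSVs to load when `simulate` is off.
#' @param plate_path QM-MSP plate export for the `quantify` stage.
#' @param qc_threshold copy-number QC threshold.
#' @param marker marker gene for cutpoints/models/validation.
#' @param cutoffs diagnostic positivity cutoffs (percent).
#' @param min_group_frac,min_events cutpoint-search floors.
#' @param n_splits,train_frac cross-validation parameters.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed,
                            stages = c("simulate", "diagnose",
                                       "functional_form", "cutpoints",
                                       "models", "validate"),
                            cancer_config = default_config("PCa1"),
                            benign_config = default_config("BPH"),
                            cohort_path = NULL, benign_path = NULL,
                            plate_path = NULL, qc_threshold = 3000,
                            marker = "GSTP1", cutoffs = c(1, 2),
                            min_group_frac = 0.10, min_events = 5,
                            n_splits = 200, train_frac = 0.80) {
  if (missing(seed)) stop("seed is mandatory for any stochastic stage")
  known <- c("simulate", "quantify", "diagnose", "functional_form",
             "cutpoints", "models", "validate")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (p in c(cohort_path, benign_path, plate_path))
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  structure(
    list(output_dir = output_dir, seed = seed, stages = stages,
         cancer_config = cancer_config, benign_config = benign_config,
         cohort_path = cohort_path, benign_path = benign_path,
         plate_path = plate_path, qc_threshold = qc_threshold,
         marker = marker, cutoffs = cutoffs,
         min_group_frac = min_group_frac, min_events = min_events,
         n_splits = n_splits, train_frac = train_frac),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys matching the [pipeline_config()] arguments; the two cohort
#' configurations can be given as `cancer_cohort` / `benign_cohort` names
#' (`"PCa1"`, `"PCa2"`, `"BPH"`) with optional `n_cancer` / `n_benign`
#' overrides. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c(setdiff(names(formals(pipeline_config)),
                       c("cancer_config", "benign_config")),
               "cancer_cohort", "benign_cohort", "n_cancer", "n_benign")
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  seed <- raw$seed %||% stop("seed is mandatory")
  args <- raw[setdiff(names(raw),
                      c("cancer_cohort", "benign_cohort", "n_cancer",
                        "n_benign"))]
  if (!is.null(raw$cutoffs)) args$cutoffs <- unlist(raw$cutoffs)
  if (!is.null(raw$stages)) args$stages <- unlist(raw$stages)
  args$cancer_config <- default_config(raw$cancer_cohort %||% "PCa1",
                                       n_patients = raw$n_cancer,
                                       seed = seed)
  args$benign_config <- default_config(raw$benign_cohort %||% "BPH",
                                       n_patients = raw$n_benign,
                                       seed = seed)
  do.call(pipeline_config, args)
}

.write_table <- function(d, dir, name) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) signif(x, 6))
  utils::write.csv(d, file.path(dir, name), row.names = FALSE, na = "NA")
}

#' Run the end-to-end analysis pipeline
#'
#' Sequences the enabled stages -- simulate, quantify, diagnose, functional
#' form, cutpoints, prognostic models (with Kaplan-Meier/log-rank), and the
#' cross-validated CPE comparison -- writing one delimited table per stage
#' under `config$output_dir` (floating values at 6 significant digits) plus
#' a machine-readable `run_log.json` recording all parameters and seeds.
#' A stage failure aborts with the failing stage named; tables written by
#' earlier stages are retained. Deterministic given the configured seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  paths <- character(0)
  log <- list(seed = config$seed, stages = config$stages,
              marker = config$marker, cutoffs = config$cutoffs,
              min_group_frac = config$min_group_frac,
              min_events = config$min_events,
              n_splits = config$n_splits, train_frac = config$train_frac,
              qc_threshold = config$qc_threshold,
              package_version = as.character(utils::packageVersion("methstrat")))
  stage <- function(name, expr) {
    if (!name %in% config$stages) return(NULL)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(d, name) {
    .write_table(d, config$output_dir, name)
    paths <<- c(paths, file.path(config$output_dir, name))
  }

  stage("simulate", {
    out$cohort <- simulate_cohort(config$cancer_config)
    out$benign <- simulate_cohort(config$benign_config)
    write_cohort(out$cohort, file.path(config$output_dir, "cohort.csv"))
    write_cohort(out$benign, file.path(config$output_dir, "benign.csv"))
    paths <- c(paths, file.path(config$output_dir,
                                c("cohort.csv", "benign.csv")))
    log$cohort_seed <- config$cancer_config$seed
    log$benign_seed <- config$benign_config$seed
  })
  if (is.null(out$cohort) && !is.null(config$cohort_path))
    out$cohort <- read_cohort(config$cohort_path)
  if (is.null(out$benign) && !is.null(config$benign_path))
    out$benign <- read_cohort(config$benign_path)

  stage("quantify", {
    wells <- read_plate(config$plate_path %||%
                          stop("quantify stage needs plate_path"))
    out$calls <- quantify_plate(wells, config$qc_threshold)
    emit(out$calls, "methylation_calls.csv")
  })

  need_cohort <- function(name) {
    if (is.null(out$cohort))
      stop("stage '", name, "' needs a cohort (enable simulate or set ",
           "cohort_path)", call. = FALSE)
  }

  stage("diagnose", {
    need_cohort("diagnose")
    if (is.null(out$benign))
      stop("stage 'diagnose' needs a benign cohort", call. = FALSE)
    genes <- intersect(config$cancer_config$gene_names, names(out$cohort))
    out$diagnostics <- diagnostic_summary(out$benign, out$cohort,
                                          genes = genes,
                                          cutoffs = config$cutoffs)
    emit(out$diagnostics, "diagnostics.csv")
  })

  stage("functional_form", {
    need_cohort("functional_form")
    genes <- intersect(config$cancer_config$gene_names, names(out$cohort))
    rows <- lapply(genes, function(g) {
      sc <- tryCatch(functional_form_scan(out$cohort, g),
                     error = function(e) NULL)
      if (is.null(sc))
        return(data.frame(gene = g, verdict = NA_character_,
                          quad_p = NA_real_, spline_p = NA_real_))
      data.frame(gene = g, verdict = sc$verdict,
                 quad_p = sc$quadratic_vs_linear$p_value,
                 spline_p = sc$spline_vs_linear$p_value)
    })
    out$functional_form <- do.call(rbind, rows)
    emit(out$functional_form, "functional_form.csv")
  })

  stage("cutpoints", {
    need_cohort("cutpoints")
    out$rule <- two_stage_cutpoint_search(
      out$cohort, config$marker, min_group_frac = config$min_group_frac,
      min_events = config$min_events)
    prof <- rbind(
      cbind(stage = "dichotomize", attr(out$rule, "stage1")$profile),
      cbind(stage = "trichotomize", attr(out$rule, "stage2")$profile))
    emit(prof, "cutpoint_profile.csv")
    emit(data.frame(cut1 = out$rule$cut1, cut2 = out$rule$cut2),
         "cutpoints.csv")
  })

  stage("models", {
    need_cohort("models")
    rule <- out$rule %||% trichotomy_rule(15, 50)
    out$models <- build_prognostic_models(out$cohort, rule,
                                      marker = config$marker)
    emit(out$models$table, "prognostic_models.csv")
    grp <- classify(out$cohort[[config$marker]], rule)
    keep <- !is.na(grp)
    sp <- split(out$cohort[keep, c("followup_years", "cf_event")],
                grp[keep])
    km <- do.call(rbind, Map(function(g, d) {
      cbind(group = g, km_estimate(d$followup_years, d$cf_event))
    }, names(sp), sp))
    rownames(km) <- NULL
    out$logrank <- logrank_test(out$cohort$followup_years[keep],
                                out$cohort$cf_event[keep], grp[keep])
    lmhm <- ifelse(grp[keep] == "MM", "MM", "LM+HM")
    out$logrank_lmhm <- logrank_test(out$cohort$followup_years[keep],
                                     out$cohort$cf_event[keep], lmhm)
    emit(km, "km_curves.csv")
    emit(data.frame(
      contrast = c("LM/MM/HM", "MM vs LM+HM"),
      chisq = c(out$logrank$statistic, out$logrank_lmhm$statistic),
      df = c(out$logrank$df, out$logrank_lmhm$df),
      p = c(out$logrank$p_value, out$logrank_lmhm$p_value)),
      "logrank.csv")
  })

  stage("validate", {
    need_cohort("validate")
    clinical <- c("pt_high", "gleason_high", "psa")
    rule0 <- trichotomy_rule(15, 50)  # coding only; CV re-tunes per split
    covs <- .model_covariates(out$cohort, rule0, config$marker)
    d <- cbind(out$cohort, covs[, c("pt_high", "gleason_high")])
    out$cv <- cv_compare(
      d, model_spec(clinical, methylation = FALSE),
      model_spec(clinical, methylation = TRUE, marker = config$marker),
      n_splits = config$n_splits, train_frac = config$train_frac,
      seed = config$seed, min_group_frac = config$min_group_frac,
      min_events = config$min_events)
    emit(data.frame(
      model = c("clinical", "clinical + methylation"),
      mean_cpe = c(out$cv$mean_a, out$cv$mean_b),
      halfwidth = c(out$cv$halfwidth_a, out$cv$halfwidth_b),
      paired_t = out$cv$paired_t$statistic,
      paired_p = out$cv$paired_t$p_value,
      n_splits = out$cv$n_splits), "cv_validation.csv")
    emit(out$cv$per_split, "cv_splits.csv")
  })

  jsonlite::write_json(log, file.path(config$output_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, file.path(config$output_dir, "run_log.json"))
  invisible(c(out, list(paths = paths)))
}
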