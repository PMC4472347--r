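#' Percent methylation from QM-MSP copy counts
#'
#' The assay quantifies methylated (M) and unmethylated (U) template copies
#' separately after a methylation-independent pre-amplification; total DNA is
#' their sum, and percent methylation is `100 * M / (M + U)`. Copy numbers
#' are accepted as non-negative reals (qPCR standard-curve interpolation
#' yields fractional copies). Vectorized.
#'
#' @param M,U non-negative methylated / unmethylated copy numbers.
#' @return percent methylation in \[0, 100\].
#' @export
percent_methylation <- function(M, U) {
  if (any(M < 0) || any(U < 0)) stop("copy numbers must be non-negative")
  tot <- M + U
  if (any(tot == 0))
    stop("undefined measurement: M + U = 0 (no amplifiable template)")
  100 * M / tot
}

#' Copy-number quality-control filter
#'
#' A sample x gene well is accepted for quantification only when it contains
#' strictly more than `threshold` gene copies after pre-amplification
#' (default 3000). Applied per gene, not summed over genes.
#'
#' @inheritParams percent_methylation
#' @param threshold positive copy-number threshold.
#' @return logical: `TRUE` iff `M + U > threshold`.
#' @export
qc_filter <- function(M, U, threshold = 3000) {
  if (any(M < 0) || any(U < 0)) stop("copy numbers must be non-negative")
  stopifnot(threshold > 0)
  (M + U) > threshold
}

#' Quantify a QM-MSP plate
#'
#' Computes one methylation call per well: percent methylation only for
#' wells passing the copy-number filter, `NA` otherwise. Rejected-well counts
#' are reported via `message()` and attached as an attribute.
#'
#' @param wells data.frame with columns `sample_id`, `gene`,
#'   `methylated_copies`, `unmethylated_copies`; `(sample_id, gene)` pairs
#'   must be unique.
#' @param threshold copy-number QC threshold, see [qc_filter()].
#' @return data.frame with `sample_id`, `gene`, `total_copies`, `qc_pass`,
#'   `percent`; attribute `n_rejected` counts QC failures.
#' @export
quantify_plate <- function(wells, threshold = 3000) {
  need <- c("sample_id", "gene", "methylated_copies", "unmethylated_copies")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stop("wells is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(wells) == 0L) {
    out <- data.frame(sample_id = character(0), gene = character(0),
                      total_copies = numeric(0), qc_pass = logical(0),
                      percent = numeric(0))
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  key <- paste(wells$sample_id, wells$gene, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (sample_id, gene) pair: ",
         gsub("\r", " / ", dup, fixed = TRUE))
  }
  M <- wells$methylated_copies
  U <- wells$unmethylated_copies
  qc <- qc_filter(M, U, threshold)
  tot <- M + U
  pct <- rep(NA_real_, nrow(wells))
  pct[qc] <- percent_methylation(M[qc], U[qc])  # qc implies tot > 0
  out <- data.frame(sample_id = wells$sample_id, gene = wells$gene,
                    total_copies = tot, qc_pass = qc, percent = pct,
                    stringsAsFactors = FALSE)
  n_rej <- sum(!qc)
  if (n_rej > 0)
    message(n_rej, " of ", nrow(wells),
            " wells rejected by the >", threshold, "-copy filter")
  attr(out, "n_rejected") <- n_rej
  out
}

#' Read a QM-MSP plate export
#'
#' Delimited text with columns `sample_id`, `gene`, `methylated_copies`,
#' `unmethylated_copies`.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return data.frame of well measurements.
#' @export
read_plate <- function(path, sep = ",") {
  if (!file.exists(path)) stop("plate export not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "methylated_copies", "unmethylated_copies")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("plate export is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(d$methylated_copies)) ||
        any(!is.finite(d$unmethylated_copies)))
    stop("non-numeric copy counts in plate export")
  d
}
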