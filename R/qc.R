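# Probe / sample quality control on detection p-values.
#
# A probe is removed when its detection p-value exceeds `p_threshold` in
# strictly more than `max_fail_fraction` of samples. A sample is flagged when
# strictly more than `fail_fraction` of its probes fail detection, or when
# its methylation distribution is an outlier. Intensity-level outlier
# statistics are not available from beta values; the outlier rule is a
# deliberate beta-scale approximation: a sample is an outlier when its mean
# beta deviates from the cohort mean of per-sample means by at least
# `outlier_sd` standard deviations (sample s.d. over the per-sample means).

#' Probe-level detection QC
#'
#' @param detp Detection p-value matrix (probes x samples).
#' @param p_threshold Detection p-value above which a measurement counts as
#'   failed (default 0.01).
#' @param max_fail_fraction A probe is removed when its fraction of failed
#'   samples is strictly greater than this (default 0.05).
#' @return List with `keep` (named logical vector over probes),
#'   `removed_probes` (ids) and `fail_fraction` (per-probe fraction).
#' @export
probe_qc <- function(detp, p_threshold = 0.01, max_fail_fraction = 0.05) {
  stop_if(!is.matrix(detp) || nrow(detp) == 0L || ncol(detp) == 0L,
          "'detp' must be a non-empty matrix")
  stop_if(any(!is.finite(detp)), "non-finite detection p-values")
  frac <- rowMeans(detp > p_threshold)
  keep <- frac <= max_fail_fraction
  list(keep = keep,
       removed_probes = rownames(detp)[!keep],
       fail_fraction = frac)
}

#' Sample-level detection and distribution QC
#'
#' @param detp Detection p-value matrix.
#' @param betas Beta matrix on the same axes.
#' @param p_threshold Failed-measurement threshold (default 0.01).
#' @param fail_fraction A sample is flagged when its failed-probe fraction is
#'   strictly greater than this (default 0.01).
#' @param outlier_sd Outlier flag when the sample's mean beta deviates at
#'   least this many standard deviations from the cohort mean of per-sample
#'   means (default 3).
#' @return List with `flagged_samples` (ids), `reason` (named character:
#'   `"fail_fraction"`, `"outlier_distribution"` or both comma-joined) and
#'   per-sample `fail_fraction` / `mean_beta`.
#' @export
sample_qc <- function(detp, betas, p_threshold = 0.01, fail_fraction = 0.01,
                      outlier_sd = 3) {
  stop_if(!identical(dim(detp), dim(betas)),
          "'detp' and 'betas' must have identical dimensions")
  stop_if(!is.null(rownames(detp)) && !is.null(rownames(betas)) &&
            !identical(rownames(detp), rownames(betas)),
          "'detp' and 'betas' probe ids disagree")
  stop_if(ncol(betas) < 3L, "sample QC needs at least 3 samples")
  frac <- colMeans(detp > p_threshold)
  mb <- colMeans(betas, na.rm = TRUE)
  sd_mb <- stats::sd(mb)
  outlier <- if (is.na(sd_mb) || sd_mb == 0) rep(FALSE, length(mb))
             else abs(mb - mean(mb)) >= outlier_sd * sd_mb
  bad_frac <- frac > fail_fraction
  flagged <- bad_frac | outlier
  reason <- mapply(function(f, o)
    paste(c(if (f) "fail_fraction", if (o) "outlier_distribution"),
          collapse = ","),
    bad_frac, outlier)
  ids <- colnames(betas) %||% as.character(seq_along(mb))
  list(flagged_samples = ids[flagged],
       reason = stats::setNames(reason[flagged], ids[flagged]),
       fail_fraction = stats::setNames(frac, ids),
       mean_beta = stats::setNames(mb, ids))
}

#' Run probe then sample QC and subset the matrices
#'
#' Single-pass application of the two rules (probes first, then samples;
#' `order = "samples_first"` reverses this).
#'
#' @param betas Beta matrix. @param detp Detection p-value matrix.
#' @param order `"probes_first"` (default) or `"samples_first"`.
#' @param ... Passed on to [probe_qc()] and [sample_qc()].
#' @return List with filtered `betas`, `detp`, and a `report` combining the
#'   two QC outputs (serialisable with [write_qc_report()]).
#' @export
run_qc <- function(betas, detp, order = c("probes_first", "samples_first"),
                   ...) {
  order <- match.arg(order)
  dots <- list(...)
  pq_args <- dots[names(dots) %in% c("p_threshold", "max_fail_fraction")]
  sq_args <- dots[names(dots) %in% c("p_threshold", "fail_fraction", "outlier_sd")]
  if (order == "probes_first") {
    pq <- do.call(probe_qc, c(list(detp), pq_args))
    detp <- detp[pq$keep, , drop = FALSE]
    betas <- betas[pq$keep, , drop = FALSE]
    sq <- do.call(sample_qc, c(list(detp, betas), sq_args))
    keep_s <- !(colnames(betas) %in% sq$flagged_samples)
  } else {
    sq <- do.call(sample_qc, c(list(detp, betas), sq_args))
    keep_s <- !(colnames(betas) %in% sq$flagged_samples)
    detp <- detp[, keep_s, drop = FALSE]
    betas <- betas[, keep_s, drop = FALSE]
    pq <- do.call(probe_qc, c(list(detp), pq_args))
    detp <- detp[pq$keep, , drop = FALSE]
    betas <- betas[pq$keep, , drop = FALSE]
    keep_s <- rep(TRUE, ncol(betas))
  }
  if (order == "probes_first") {
    detp <- detp[, keep_s, drop = FALSE]
    betas <- betas[, keep_s, drop = FALSE]
  }
  list(betas = betas, detp = detp,
       report = list(removed_probes = pq$removed_probes,
                     probe_fail_fraction = pq$fail_fraction,
                     flagged_samples = sq$flagged_samples,
                     flag_reason = as.list(sq$reason),
                     sample_fail_fraction = sq$fail_fraction))
}

#' Write a QC report as JSON
#'
#' @param report The `report` element of [run_qc()].
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
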