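# Published episignature probe lists: ingestion, intersection with the
# post-QC array content, and case-control delta-beta reproducibility.

#' Construct an episignature definition
#'
#' @param name Signature label (a syndrome may have several signatures).
#' @param syndrome Syndrome / gene label the signature targets.
#' @param probe_ids Unique CpG probe identifiers.
#' @param source Free-text citation of the publication the list came from.
#' @param x_linked Is the target gene X-linked? Sensitivity is then computed
#'   on male carriers.
#' @return An `episignature` list.
#' @export
episignature <- function(name, syndrome = name, probe_ids, source = "",
                         x_linked = FALSE) {
  probe_ids <- as.character(probe_ids)
  stop_if(length(probe_ids) == 0L, "'probe_ids' must be non-empty")
  if (anyDuplicated(probe_ids)) {
    warning("duplicated probe ids in signature '", name, "' deduplicated",
            call. = FALSE)
    probe_ids <- unique(probe_ids)
  }
  structure(list(name = name, syndrome = syndrome, probe_ids = probe_ids,
                 source = source, x_linked = x_linked),
            class = "episignature")
}

#' @export
print.episignature <- function(x, ...) {
  cat(sprintf("Episignature '%s' (%s%s): %d probes\n", x$name, x$syndrome,
              if (x$x_linked) ", X-linked" else "", length(x$probe_ids)))
  invisible(x)
}

#' Load episignature probe lists from CSV
#'
#' Expects columns `signature` and `probe_id`; optional columns `syndrome`,
#' `source` and `x_linked` are carried through. One definition is returned
#' per distinct signature name; duplicate probes within a signature are
#' dropped with a warning.
#'
#' @param path CSV file path.
#' @return Named list of [episignature()] objects.
#' @export
load_signatures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("signature", "probe_id") %in% names(df)),
          "probe-list CSV needs columns 'signature' and 'probe_id'")
  stop_if(nrow(df) == 0L, "empty probe-list file: ", path)
  out <- lapply(split(df, factor(df$signature, levels = unique(df$signature))),
                function(d) episignature(
                  name = d$signature[1L],
                  syndrome = if ("syndrome" %in% names(d)) d$syndrome[1L]
                             else d$signature[1L],
                  probe_ids = d$probe_id,
                  source = if ("source" %in% names(d)) d$source[1L] else "",
                  x_linked = if ("x_linked" %in% names(d))
                    isTRUE(as.logical(d$x_linked[1L])) else FALSE))
  out
}

#' Restrict a signature to the probes present after QC
#'
#' @param def An [episignature()].
#' @param kept_probes Character vector of probe ids retained by [probe_qc()]
#'   (or the rownames of the post-QC beta matrix).
#' @return List with `def` (the restricted signature, original size kept in
#'   attribute `"n_original"`) and `pct_retained` (percentage).
#' @export
intersect_with_array <- function(def, kept_probes) {
  stop_if(!inherits(def, "episignature"), "'def' must be an episignature")
  present <- def$probe_ids %in% kept_probes
  stop_if(!any(present),
          "signature '", def$name, "' has no probe left after QC; unevaluable")
  restricted <- def
  restricted$probe_ids <- def$probe_ids[present]
  attr(restricted, "n_original") <- length(def$probe_ids)
  list(def = restricted, pct_retained = 100 * mean(present))
}

#' Case-control delta-beta gap of a signature
#'
#' For every retained signature probe, the gap is the difference between the
#' mean beta of the syndrome's validation cases and the mean beta of the
#' controls. The reported fractions count probes whose absolute gap is
#' strictly greater than each threshold (so a probe sitting exactly on a
#' threshold does not meet it). For X-linked signatures only male cases
#' enter the case mean by default, matching the sensitivity restriction.
#'
#' @param betas Beta matrix (normalized scale by default; pass residuals for
#'   the adjusted-scale variant).
#' @param sheet Sample sheet.
#' @param def An [episignature()] (typically post-[intersect_with_array()]).
#' @param thresholds Absolute-gap thresholds (default `c(0.05, 0.10)`).
#' @param males_only_if_x_linked Restrict X-linked case means to males
#'   (default TRUE).
#' @return A `data.frame` (one row) with signature name, probe counts and
#'   the fraction of probes exceeding each threshold (columns `frac_gt_005`,
#'   `frac_gt_010` for the defaults), plus `delta_beta` attribute holding
#'   the per-probe gaps.
#' @export
delta_beta_gap <- function(betas, sheet, def, thresholds = c(0.05, 0.10),
                           males_only_if_x_linked = TRUE) {
  stop_if(!inherits(def, "episignature"), "'def' must be an episignature")
  probes <- intersect(def$probe_ids, rownames(betas))
  stop_if(length(probes) == 0L, "no signature probe present in 'betas'")
  al <- .align_sheet(betas, sheet)
  betas <- al$m
  sheet <- al$sheet
  is_case <- sheet$role == "case" & !is.na(sheet$syndrome) &
    sheet$syndrome == def$syndrome
  if (def$x_linked && males_only_if_x_linked)
    is_case <- is_case & sheet$sex == "M"
  is_control <- sheet$role == "control"
  stop_if(!any(is_case), "no case of syndrome '", def$syndrome, "'")
  stop_if(!any(is_control), "no control sample")
  sub <- betas[probes, , drop = FALSE]
  db <- rowMeans(sub[, is_case, drop = FALSE]) -
    rowMeans(sub[, is_control, drop = FALSE])
  res <- data.frame(signature = def$name, syndrome = def$syndrome,
                    n_probes_original = attr(def, "n_original") %||% length(def$probe_ids),
                    n_probes_retained = length(probes),
                    stringsAsFactors = FALSE)
  res$pct_retained <- 100 * res$n_probes_retained / res$n_probes_original
  for (t in sort(thresholds))
    res[[sprintf("frac_gt_%03.0f", 100 * t)]] <- mean(abs(db) > t)
  attr(res, "delta_beta") <- db
  res
}

#' Table of gap metrics over several signatures
#'
#' @param betas,sheet,thresholds As in [delta_beta_gap()].
#' @param defs List of [episignature()] objects.
#' @param kept_probes Optional post-QC probe universe; defaults to the
#'   rownames of `betas`.
#' @return A `data.frame`, one row per signature.
#' @export
gap_table <- function(betas, sheet, defs, kept_probes = rownames(betas),
                      thresholds = c(0.05, 0.10)) {
  do.call(rbind, lapply(defs, function(d) {
    r <- intersect_with_array(d, kept_probes)
    delta_beta_gap(betas, sheet, r$def, thresholds)
  }))
}
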