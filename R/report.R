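# Assembly of the final evaluation bundle: reproducibility (gap) table,
# per-parametrization performance table with exact CIs, projection summaries
# and the per-VUS call table with intermediate / conflicting flags.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble and write the evaluation report bundle
#'
#' Emits `gap_table.tsv`, `performance.tsv`, `projections.tsv`, and (when
#' test samples were classified) `vus_calls.tsv`, plus a `manifest.json`
#' index, into `dir`. In the VUS table, a sample called positive by one
#' signature of a syndrome but not by another signature of the same syndrome
#' is flagged `conflicting`.
#'
#' @param gap Gap-metric table from [gap_table()].
#' @param perf A `performance_report` from [evaluate_signatures()] /
#'   [loo_evaluate()].
#' @param projections List of [signature_pca()] results (optional).
#' @param vus_calls Stacked [classify_test_samples()] output (optional).
#' @param dir Output directory.
#' @return The report bundle (list), invisibly; side effect: files in `dir`.
#' @export
build_report <- function(gap, perf, projections = NULL, vus_calls = NULL,
                         dir = NULL) {
  sigs <- unique(gap$signature)
  stop_if(!all(unique(perf$summary$signature) %in% sigs),
          "performance table contains signatures absent from the gap table: ",
          paste(setdiff(unique(perf$summary$signature), sigs), collapse = ", "))
  proj_df <- NULL
  if (length(projections)) {
    pr_sigs <- vapply(projections, `[[`, character(1), "signature")
    stop_if(!all(pr_sigs %in% sigs),
            "projection results for unknown signature(s): ",
            paste(setdiff(pr_sigs, sigs), collapse = ", "))
    proj_df <- do.call(rbind, lapply(projections, function(p) {
      ve <- p$variance_explained
      data.frame(signature = p$signature,
                 pc1_var_pct = 100 * ve[1L],
                 pc2_var_pct = if (length(ve) >= 2L) 100 * ve[2L] else NA_real_,
                 n_samples = nrow(p$scores), stringsAsFactors = FALSE)
    }))
  }

  if (!is.null(vus_calls) && nrow(vus_calls)) {
    stop_if(!all(unique(vus_calls$signature) %in% sigs),
            "VUS calls for unknown signature(s): ",
            paste(setdiff(unique(vus_calls$signature), sigs), collapse = ", "))
    syn_of <- stats::setNames(gap$syndrome, gap$signature)
    vus_calls$syndrome <- unname(syn_of[vus_calls$signature])
    pos <- !(vus_calls$call %in% c("control", "no_call"))
    key <- paste(vus_calls$sample_id, vus_calls$syndrome)
    conflicting <- stats::ave(pos, key, FUN = function(p)
      rep(length(unique(p)) > 1L, length(p)))
    vus_calls$conflicting <- as.logical(conflicting)
  } else {
    vus_calls <- NULL
  }

  # Display-rounded performance columns alongside the raw proportions.
  perf_tab <- perf$summary
  for (p in c("sens", "spec", "inter_spec"))
    perf_tab[[paste0(p, "_display")]] <- mapply(
      format_ci, perf_tab[[paste0(p, "_x")]], perf_tab[[paste0(p, "_n")]])

  bundle <- list(gap = gap, performance = perf_tab, projections = proj_df,
                 vus_calls = vus_calls, calls = perf$calls)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(gap_table = "gap_table.tsv", performance = "performance.tsv")
    .write_tsv(gap, file.path(dir, "gap_table.tsv"))
    .write_tsv(perf_tab, file.path(dir, "performance.tsv"))
    if (!is.null(proj_df)) {
      .write_tsv(proj_df, file.path(dir, "projections.tsv"))
      files$projections <- "projections.tsv"
    }
    if (!is.null(vus_calls)) {
      .write_tsv(vus_calls, file.path(dir, "vus_calls.tsv"))
      files$vus_calls <- "vus_calls.tsv"
    }
    manifest <- list(created = format(Sys.time(), tz = "UTC"),
                     n_signatures = length(sigs), files = files)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(bundle)
}
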