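# Plain-text interchange formats:
#   beta / detection-p matrices : TSV, first column "probe_id", one column
#     per sample (GEO series-matrix-like layout)
#   sample sheet                : CSV (sample_id, role, syndrome, sex,
#     age_years, cell_frac_1..6, batch, ...)
#   probe lists                 : CSV (signature, probe_id)
# Numerics are written with 17 significant digits so doubles round-trip
# bit-identically.

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_matrix_tsv <- function(m, path) {
  ch <- matrix(.fmt_num(m), nrow = nrow(m), ncol = ncol(m))
  df <- data.frame(probe_id = rownames(m), ch, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beta-value (or detection p-value) matrix from TSV
#'
#' Expects a header line and a first `probe_id` column; remaining columns are
#' samples.
#'
#' @param path File path.
#' @return Numeric matrix, probes in rows (rownames), samples in columns.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if(names(df)[1L] != "probe_id", "first column must be 'probe_id'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$probe_id
  m
}

#' @rdname read_beta_matrix
#' @export
read_detp_matrix <- read_beta_matrix

#' Read a sample sheet from CSV
#'
#' @param path File path.
#' @return A `data.frame` with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("sample_id", "role") %in% names(df)),
          "sample sheet must have 'sample_id' and 'role' columns")
  df
}

.write_sample_sheet <- function(sheet, path) {
  out <- sheet
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], .fmt_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `betas.tsv`, `sample_sheet.csv`, `signatures.csv` and `detp.tsv`;
#' all matrices round-trip bit-identically through [read_beta_matrix()] /
#' [read_sample_sheet()] / [load_signatures()].
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stop_if(!inherits(cohort, "synthetic_cohort"),
          "'cohort' must come from generate_cohort()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stop_if(!dir.exists(dir), "cannot create directory: ", dir)
  paths <- c(betas = file.path(dir, "betas.tsv"),
             sheet = file.path(dir, "sample_sheet.csv"),
             signatures = file.path(dir, "signatures.csv"),
             detp = file.path(dir, "detp.tsv"))
  .write_matrix_tsv(cohort$betas, paths[["betas"]])
  .write_sample_sheet(cohort$sheet, paths[["sheet"]])
  sig_df <- do.call(rbind, lapply(cohort$signatures, function(s)
    data.frame(signature = s$name, probe_id = s$probe_ids,
               stringsAsFactors = FALSE)))
  if (is.null(sig_df))
    sig_df <- data.frame(signature = character(), probe_id = character())
  utils::write.csv(sig_df, paths[["signatures"]], row.names = FALSE,
                   quote = FALSE)
  .write_matrix_tsv(cohort$detp, paths[["detp"]])
  invisible(paths)
}
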