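`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# Keep only the matrix columns described in the sheet, in matrix order.
.align_sheet <- function(m, sheet) {
  keep <- colnames(m) %in% sheet$sample_id
  m <- m[, keep, drop = FALSE]
  list(m = m, sheet = sheet[match(colnames(m), sheet$sample_id), ,
                            drop = FALSE])
}

#' Format a proportion with its exact binomial CI the way diagnostic reports print it
#'
#' Percentages are rounded to the nearest integer; CI bounds to the nearest
#' integer percent, or to one decimal when the denominator is 20 or fewer.
#'
#' @param x Number of successes.
#' @param n Denominator.
#' @param level Confidence level (default 0.95).
#' @return A string such as `"100% [86-100%]"`, or `"NA"` when `n` is 0.
#' @export
format_ci <- function(x, n, level = 0.95) {
  if (n == 0) return("NA")
  ci <- clopper_pearson(x, n, level)
  digits <- if (n <= 20) 1L else 0L
  sprintf("%d%% [%s-%s%%]",
          round(100 * x / n),
          format(round(100 * ci[[1L]], digits), nsmall = digits),
          format(round(100 * ci[[2L]], digits), nsmall = digits))
}
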