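# Confounder adjustment: per-probe ordinary least squares of beta on
# predicted age, sex and blood cell composition; the residuals feed all
# downstream classification and visualisation.

# Design matrix: intercept + age + sex(M=1, F=0, NA -> mean) + cell
# fractions with one column dropped (they sum to 1).
.build_design <- function(sheet, covariates) {
  n <- nrow(sheet)
  X <- matrix(1, n, 1L, dimnames = list(sheet$sample_id, "(Intercept)"))
  if ("age" %in% covariates) {
    stop_if(!"age_years" %in% names(sheet), "sample sheet lacks 'age_years'")
    X <- cbind(X, age_years = sheet$age_years)
  }
  if ("sex" %in% covariates) {
    stop_if(!"sex" %in% names(sheet), "sample sheet lacks 'sex'")
    s <- ifelse(sheet$sex == "M", 1, ifelse(sheet$sex == "F", 0, NA))
    s[is.na(s)] <- mean(s, na.rm = TRUE)
    X <- cbind(X, sex = s)
  }
  if ("cell" %in% covariates) {
    cf <- grep("^cell_frac_", names(sheet), value = TRUE)
    stop_if(length(cf) < 2L, "sample sheet lacks cell_frac_* columns")
    keep <- cf[-length(cf)]                 # drop one: compositional redundancy
    X <- cbind(X, as.matrix(sheet[, keep, drop = FALSE]))
  }
  stop_if(anyNA(X), "missing covariate values in the sample sheet")
  X
}

#' Residualize beta values on age, sex and cell composition
#'
#' Fits, for every probe, an ordinary-least-squares model
#' `beta ~ intercept + covariates` jointly on all samples (optionally on a
#' fitting subset, e.g. controls only) and returns the residuals. Missing
#' beta values are mean-imputed per probe for the fit and re-masked in the
#' output; probes missing in more than `max_missing` of samples are dropped.
#'
#' @param betas Beta matrix (probes x samples), post-QC.
#' @param sheet Sample sheet covering all columns of `betas`.
#' @param covariates Subset of `c("age", "sex", "cell")`.
#' @param fit_samples Optional sample ids on which coefficients are
#'   estimated; residuals are still returned for all samples. Default: all
#'   samples jointly.
#' @param max_missing Probes with a larger missing fraction are excluded
#'   (default 0.2).
#' @return Residual matrix on the same axes (minus excluded probes), with
#'   attribute `"design"` holding the design matrix.
#' @export
residualize <- function(betas, sheet, covariates = c("age", "sex", "cell"),
                        fit_samples = NULL, max_missing = 0.2) {
  stop_if(!is.matrix(betas), "'betas' must be a matrix")
  covariates <- match.arg(covariates, several.ok = TRUE)
  sheet <- sheet[match(colnames(betas), sheet$sample_id), , drop = FALSE]
  stop_if(anyNA(sheet$sample_id), "samples in 'betas' missing from the sheet")
  X <- .build_design(sheet, covariates)
  # Constant covariates carry no information beyond the intercept; drop them
  # so the all-constant limit degrades to plain per-probe centering.
  const <- c(FALSE, apply(X[, -1L, drop = FALSE], 2L,
                          function(v) max(v) - min(v) == 0))
  X <- X[, !const, drop = FALSE]

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  miss_frac <- rowMeans(is.na(betas))
  keep <- miss_frac <= max_missing
  betas <- betas[keep, , drop = FALSE]
  na_mask <- is.na(betas)
  if (any(na_mask)) {
    pm <- rowMeans(betas, na.rm = TRUE)
    betas[na_mask] <- pm[row(betas)[na_mask]]
  }

  Y <- t(betas)                               # samples x probes
  if (is.null(fit_samples)) {
    resid <- qr.resid(qx, Y)
  } else {
    fit_idx <- match(fit_samples, colnames(betas))
    stop_if(anyNA(fit_idx), "unknown sample id in 'fit_samples'")
    stop_if(length(fit_idx) <= ncol(X), "too few fitting samples for the design")
    qf <- qr(X[fit_idx, , drop = FALSE])
    stop_if(qf$rank < ncol(X), "design rank-deficient on the fitting subset")
    beta_hat <- qr.coef(qf, Y[fit_idx, , drop = FALSE])
    resid <- Y - X %*% beta_hat
  }
  out <- t(resid)
  out[na_mask] <- NA
  dimnames(out) <- dimnames(betas)
  structure(out, design = X)
}
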