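# Visual-diagnostic computations: PCA of signature-probe residuals and
# hierarchical-clustering orderings for heatmaps. Figures themselves are a
# renderer's concern; everything here is numeric and deterministic.

#' PCA of samples on a signature's residuals
#'
#' Principal components of the samples x signature-probes matrix, probes
#' mean-centered, unscaled. Component signs follow a deterministic
#' convention: the largest-magnitude probe loading of each component is made
#' positive.
#'
#' @param residuals Residual (or beta) matrix, probes x samples.
#' @param def An [episignature()].
#' @param n_components Number of components to retain (default 2; capped at
#'   the matrix rank).
#' @return A `signature_projection`: list with `scores` (samples x
#'   components), `loadings` (probes x components), `variance_explained`
#'   (fraction per retained component over the total variance) and
#'   `sdev_all` (all singular values / sqrt(n-1)).
#' @export
signature_pca <- function(residuals, def, n_components = 2L) {
  feats <- .restrict_features(residuals, def)
  stop_if(ncol(feats) < 3L, "PCA needs at least 3 samples")
  x <- t(feats)                       # samples x probes
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  stop_if(total_var < .Machine$double.eps * nrow(x),
          "zero variance: all samples identical on the signature probes")
  ncomp <- min(n_components, sum(pc$sdev > 1e-12 * pc$sdev[1L]), ncol(pc$x))
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  loadings <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  for (j in seq_len(ncomp)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = pc$sdev[seq_len(ncomp)]^2 / total_var,
                 sdev_all = pc$sdev, signature = def$name),
            class = "signature_projection")
}

#' @export
print.signature_projection <- function(x, ...) {
  cat(sprintf("PCA of signature '%s': %d samples\n", x$signature, nrow(x$scores)))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_along(x$variance_explained),
                            100 * x$variance_explained), collapse = ", ")))
  invisible(x)
}

#' Hierarchical-clustering orders for a signature heatmap
#'
#' Agglomerative clustering of both samples and probes (Euclidean distance,
#' complete linkage by default). For determinism under input permutation,
#' rows and columns are first put in lexicographic label order, so tie-breaks
#' depend only on the labels, not on the input ordering.
#'
#' @param residuals Residual (or beta) matrix, probes x samples.
#' @param def An [episignature()].
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @return List with `row_order` / `col_order` (probe and sample labels in
#'   leaf order), `matrix` (the reordered residuals) and the two `hclust`
#'   trees.
#' @export
cluster_heatmap <- function(residuals, def, linkage = "complete") {
  feats <- .restrict_features(residuals, def)
  stop_if(ncol(feats) < 2L, "clustering needs at least 2 samples")
  feats <- feats[order(rownames(feats)), order(colnames(feats)), drop = FALSE]
  hc_col <- stats::hclust(stats::dist(t(feats)), method = linkage)
  row_order <- rownames(feats)
  hc_row <- NULL
  if (nrow(feats) >= 2L) {
    hc_row <- stats::hclust(stats::dist(feats), method = linkage)
    row_order <- rownames(feats)[hc_row$order]
  }
  col_order <- colnames(feats)[hc_col$order]
  list(row_order = row_order, col_order = col_order,
       matrix = feats[row_order, col_order, drop = FALSE],
       row_tree = hc_row, col_tree = hc_col)
}
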