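# Multiclass consensus k-nearest-neighbour classification.
#
# A query is assigned the unique label reaching at least m votes among its k
# nearest training samples ("m/k" consensus); if no label reaches m, or two
# labels both do, no call is made. Distance ties are broken deterministically
# by ascending training-sample index so results are reproducible across
# platforms.

#' Parse "m/k" consensus parametrizations
#'
#' @param x Character vector such as `c("2/2", "3/4", "5/5")`.
#' @return List of `knn_config` lists with elements `m`, `k` and `label`.
#' @export
parse_configs <- function(x) {
  lapply(x, function(s) {
    mk <- suppressWarnings(as.integer(strsplit(s, "/", fixed = TRUE)[[1L]]))
    stop_if(length(mk) != 2L || anyNA(mk), "cannot parse consensus config: ", s)
    knn_config(k = mk[2L], m = mk[1L])
  })
}

#' Consensus kNN configuration
#'
#' @param k Number of nearest neighbours (k >= 1).
#' @param m Required concordant neighbours, 1 <= m <= k.
#' @param metric Distance metric (only `"euclidean"`).
#' @return A `knn_config` list with a display `label` like `"3/4"`.
#' @export
knn_config <- function(k, m = k, metric = "euclidean") {
  stop_if(k < 1L, "'k' must be >= 1")
  stop_if(m < 1L || m > k, "'m' must satisfy 1 <= m <= k")
  metric <- match.arg(metric)
  structure(list(k = as.integer(k), m = as.integer(m), metric = metric,
                 label = sprintf("%d/%d", m, k)),
            class = "knn_config")
}

#' Ordered nearest neighbours of a query
#'
#' @param train_features Features x training-samples matrix.
#' @param train_labels Label per training sample.
#' @param query Feature vector (same probe order as `train_features` rows).
#' @param k Number of neighbours to return.
#' @param metric Only `"euclidean"`.
#' @return List with `labels` and `distances`, both ordered by ascending
#'   distance, ties broken by ascending training-sample index.
#' @export
knn_votes <- function(train_features, train_labels, query, k,
                      metric = "euclidean") {
  metric <- match.arg(metric)
  stop_if(!is.matrix(train_features) || ncol(train_features) == 0L,
          "empty training set")
  stop_if(length(train_labels) != ncol(train_features),
          "one label per training sample required")
  stop_if(length(query) != nrow(train_features),
          "query dimension does not match training features")
  stop_if(k > ncol(train_features), "'k' exceeds the training-set size")
  d <- sqrt(colSums((train_features - query)^2))
  ord <- order(d, seq_along(d))[seq_len(k)]
  list(labels = train_labels[ord], distances = unname(d[ord]))
}

#' Consensus call from ordered neighbour labels
#'
#' @param neighbour_labels Labels of the k nearest neighbours.
#' @param m Required number of concordant neighbours.
#' @return The unique label reaching at least `m` votes, or `"no_call"` when
#'   none does or when two labels both do (a tie).
#' @export
consensus_call <- function(neighbour_labels, m) {
  stop_if(length(neighbour_labels) == 0L, "empty neighbour label list")
  stop_if(m > length(neighbour_labels), "'m' exceeds the number of neighbours")
  votes <- table(neighbour_labels)
  winners <- names(votes)[votes >= m]
  if (length(winners) == 1L) winners else "no_call"
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile closed form; the lower bound is 0 when no successes are
#' observed and the upper bound 1 when all trials succeed.
#'
#' @param successes Number of successes (0 <= successes <= n).
#' @param n Number of trials (n >= 1).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)` on the proportion scale.
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  stop_if(n < 1L || successes < 0L || successes > n, "invalid counts")
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0 else stats::qbeta(a, successes, n - successes + 1)
  upper <- if (successes == n) 1 else stats::qbeta(1 - a, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}
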