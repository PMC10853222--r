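# Independent brute-force oracles and small fixture builders. The oracles
# deliberately recompute everything with naive loops so they share no code
# path with the package implementation.

# Naive consensus-kNN call for one query: all distances via an explicit loop.
brute_knn_call <- function(train, labels, query, k, m) {
  d <- numeric(ncol(train))
  for (j in seq_len(ncol(train))) {
    s <- 0
    for (i in seq_len(nrow(train))) s <- s + (train[i, j] - query[i])^2
    d[j] <- sqrt(s)
  }
  ord <- order(d, seq_along(d))
  top <- labels[ord[seq_len(k)]]
  counts <- sapply(unique(top), function(l) sum(top == l))
  win <- names(counts)[counts >= m]
  if (length(win) == 1L) win else "no_call"
}

# Naive leave-one-out loop over every sample.
brute_loo_calls <- function(features, labels, k, m) {
  n <- ncol(features)
  out <- character(n)
  for (i in seq_len(n))
    out[i] <- brute_knn_call(features[, -i, drop = FALSE], labels[-i],
                             features[, i], k, m)
  names(out) <- colnames(features)
  out
}

# Normal-equations OLS residuals via explicit matrix inversion.
brute_ols_residuals <- function(Y, X) {
  # Y samples x probes, X samples x covariates
  B <- solve(t(X) %*% X) %*% t(X) %*% Y
  Y - X %*% B
}

# Minimal sample sheet for hand-built feature matrices.
toy_sheet <- function(ids, roles, syndromes = NA_character_,
                      sexes = "M", ages = 10) {
  n <- length(ids)
  df <- data.frame(sample_id = ids, role = roles,
                   syndrome = rep_len(syndromes, n),
                   sex = rep_len(sexes, n), age_years = rep_len(ages, n),
                   stringsAsFactors = FALSE)
  for (j in 1:6) df[[paste0("cell_frac_", j)]] <- 1 / 6
  df$batch <- "chip1"
  df
}

# Feature matrix where each sample sits at a given 1-D position, replicated
# over n_probes probes (so Euclidean distance is sqrt(n_probes) * |gap|).
toy_features <- function(positions, ids, n_probes = 5L) {
  m <- matrix(rep(positions, each = n_probes), nrow = n_probes,
              dimnames = list(sprintf("cg%03d", seq_len(n_probes)), ids))
  m
}

# Small strong-effect cohort used by several tests (kept modest for speed).
strong_cohort <- function(seed = 1L, n_syndromes = 1L, n_background = 300L,
                          ...) {
  syn <- lapply(paste0("S", seq_len(n_syndromes)), syndrome_spec)
  generate_cohort(cohort_config(syn, n_background_probes = n_background,
                                n_controls = 25L, seed = seed, ...))
}

control_ids <- function(sheet) sheet$sample_id[sheet$role == "control"]
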