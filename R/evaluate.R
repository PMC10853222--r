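# Leave-one-out performance estimation and test-set (VUS) classification.
#
# For each signature, a multiclass kNN over the full validation set (all
# syndromes' cases plus controls, features restricted to the signature's
# probes) predicts every validation sample from all remaining ones.
# Tallies follow the conventions of stringent-consensus diagnostics:
#   sensitivity              cases of the signature's syndrome called that
#                            syndrome (male carriers only when X-linked);
#   specificity              controls NOT assigned any syndrome (a control
#                            or no-call prediction is a true negative);
#   inter-syndrome spec.     carriers of other syndromes not assigned the
#                            evaluated syndrome.
# Each proportion is reported with an exact binomial confidence interval.

.validation_labels <- function(sheet) {
  ifelse(sheet$role == "control", "control", sheet$syndrome)
}

.restrict_features <- function(features, def) {
  probes <- intersect(def$probe_ids, rownames(features))
  stop_if(length(probes) == 0L, "no signature probe present in the features")
  features[probes, , drop = FALSE]
}

#' Leave-one-out consensus-kNN evaluation of one signature
#'
#' @param features Matrix (probes x samples) of residualized (or raw) beta
#'   values covering the validation samples.
#' @param sheet Sample sheet; rows with role `case` or `control` form the
#'   validation set.
#' @param def An [episignature()].
#' @param configs List of [knn_config()]s (or a character vector like
#'   `c("2/2", "3/4")`).
#' @param include_female_carriers Keep female carriers of an X-linked
#'   syndrome in its training folds and sensitivity denominator
#'   (default FALSE: they are excluded from this signature's evaluation).
#' @param no_call_as_negative Count a `no_call` on a control / other-syndrome
#'   carrier as a true negative (default TRUE; FALSE makes any non-control
#'   outcome, including no-calls, break specificity).
#' @param level Confidence level for the exact binomial intervals.
#' @return A `performance_report`: list with `summary` (one row per config:
#'   x/n, point estimate and CI for the three metrics) and `calls` (per
#'   sample x config call table).
#' @export
loo_evaluate <- function(features, sheet, def, configs = c("2/2", "3/3", "3/4",
                                                           "4/4", "4/5", "5/5"),
                         include_female_carriers = FALSE,
                         no_call_as_negative = TRUE, level = 0.95) {
  if (is.character(configs)) configs <- parse_configs(configs)
  stop_if(!inherits(def, "episignature"), "'def' must be an episignature")
  al <- .align_sheet(.restrict_features(features, def), sheet)
  feats <- al$m
  sheet <- al$sheet
  val <- sheet$role %in% c("case", "control")
  if (def$x_linked && !include_female_carriers)
    val <- val & !(sheet$role == "case" & sheet$syndrome == def$syndrome &
                     sheet$sex == "F")
  feats <- feats[, val, drop = FALSE]
  vs <- sheet[val, , drop = FALSE]
  labels <- .validation_labels(vs)
  stop_if(length(unique(labels)) < 2L,
          "leave-one-out evaluation needs at least 2 classes")
  kmax <- max(vapply(configs, `[[`, integer(1), "k"))
  stop_if(kmax >= ncol(feats),
          "'k' must be smaller than the validation-set size minus 1")

  n <- ncol(feats)
  calls <- matrix(NA_character_, n, length(configs),
                  dimnames = list(vs$sample_id,
                                  vapply(configs, `[[`, character(1), "label")))
  for (i in seq_len(n)) {
    nb <- knn_votes(feats[, -i, drop = FALSE], labels[-i], feats[, i], kmax)
    for (j in seq_along(configs))
      calls[i, j] <- consensus_call(nb$labels[seq_len(configs[[j]]$k)],
                                    configs[[j]]$m)
  }

  is_case <- vs$role == "case" & vs$syndrome == def$syndrome
  is_control <- vs$role == "control"
  is_other <- vs$role == "case" & vs$syndrome != def$syndrome
  tally <- function(x, n_, prefix) {
    ci <- if (n_ > 0L) clopper_pearson(x, n_, level) else c(lower = NA, upper = NA)
    stats::setNames(
      list(x, n_, if (n_ > 0L) x / n_ else NA_real_, ci[["lower"]], ci[["upper"]]),
      paste0(prefix, c("_x", "_n", "", "_lo", "_hi")))
  }
  summary <- do.call(rbind, lapply(seq_along(configs), function(j) {
    cl <- calls[, j]
    syndrome_call <- !(cl %in% c("control", "no_call"))
    neg_ok <- if (no_call_as_negative) c("control", "no_call") else "control"
    as.data.frame(c(
      list(signature = def$name, config = configs[[j]]$label),
      tally(sum(is_case & cl == def$syndrome), sum(is_case), "sens"),
      tally(sum(is_control & cl %in% neg_ok), sum(is_control), "spec"),
      tally(sum(is_other & cl != def$syndrome &
                  (no_call_as_negative | cl != "no_call")),
            sum(is_other), "inter_spec")),
      stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary,
                 calls = data.frame(sample_id = vs$sample_id, role = vs$role,
                                    syndrome = vs$syndrome, calls,
                                    check.names = FALSE,
                                    stringsAsFactors = FALSE)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  s <- x$summary
  cat("Leave-one-out consensus-kNN performance\n")
  w <- max(nchar(s$signature))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-*s %-4s sensitivity %-18s specificity %-18s inter-syndrome %s\n",
                w, s$signature[i],
                s$config[i], format_ci(s$sens_x[i], s$sens_n[i]),
                format_ci(s$spec_x[i], s$spec_n[i]),
                format_ci(s$inter_spec_x[i], s$inter_spec_n[i])))
  invisible(x)
}

#' Evaluate several signatures at several parametrizations
#'
#' @inheritParams loo_evaluate
#' @param defs List of [episignature()]s.
#' @return A `performance_report` whose `summary` and `calls` stack the
#'   per-signature results.
#' @export
evaluate_signatures <- function(features, sheet, defs,
                                configs = c("2/2", "3/3", "3/4", "4/4",
                                            "4/5", "5/5"), ...) {
  reports <- lapply(defs, loo_evaluate, features = features, sheet = sheet,
                    configs = configs, ...)
  calls <- do.call(rbind, lapply(seq_along(reports), function(i)
    cbind(signature = reports[[i]]$summary$signature[1L], reports[[i]]$calls)))
  structure(list(summary = do.call(rbind, lapply(reports, `[[`, "summary")),
                 calls = calls),
            class = "performance_report")
}

#' Classify test (VUS / clinical-hypothesis) samples
#'
#' The full validation set (no leave-one-out) is the training set; each test
#' sample receives one call under `config` (default the "3/4"
#' parametrization). A sample is flagged as an intermediate profile when it
#' gets no call, or when its `m/k` call and the stricter perfect-consensus
#' `k/k` call disagree.
#'
#' @param train_features Features x validation-samples matrix.
#' @param train_sheet Sample sheet for the validation samples.
#' @param test_features Features x test-samples matrix (same probe space).
#' @param def An [episignature()].
#' @param config A [knn_config()] or string (default `"3/4"`).
#' @param include_female_carriers See [loo_evaluate()].
#' @return A `data.frame`: sample_id, signature, call, comma-joined
#'   neighbour labels and distances, and `intermediate` flag.
#' @export
classify_test_samples <- function(train_features, train_sheet, test_features,
                                  def, config = "3/4",
                                  include_female_carriers = FALSE) {
  if (is.character(config)) config <- parse_configs(config)[[1L]]
  train <- .restrict_features(train_features, def)
  test <- .restrict_features(test_features, def)
  stop_if(!identical(rownames(train), rownames(test)),
          "train/test probe sets disagree")
  al <- .align_sheet(train, train_sheet)
  train <- al$m
  sheet <- al$sheet
  val <- sheet$role %in% c("case", "control")
  if (def$x_linked && !include_female_carriers)
    val <- val & !(sheet$role == "case" & sheet$syndrome == def$syndrome &
                     sheet$sex == "F")
  train <- train[, val, drop = FALSE]
  labels <- .validation_labels(sheet[val, , drop = FALSE])
  out <- lapply(seq_len(ncol(test)), function(i) {
    nb <- knn_votes(train, labels, test[, i], config$k)
    call <- consensus_call(nb$labels, config$m)
    strict <- consensus_call(nb$labels, config$k)
    data.frame(sample_id = colnames(test)[i], signature = def$name,
               call = call,
               neighbours = paste(nb$labels, collapse = ","),
               distances = paste(sprintf("%.6g", nb$distances), collapse = ","),
               intermediate = call == "no_call" || call != strict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
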