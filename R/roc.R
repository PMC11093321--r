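#' ROC curve and AUC for a per-site score against binary labels
#'
#' Sweeps a decision threshold over all distinct score values (sites with
#' score at or above the threshold are called deleterious), records the
#' (false-positive rate, true-positive rate) curve, and computes the AUC by
#' the trapezoidal rule. With ties grouped per threshold this equals the
#' tie-corrected Mann-Whitney statistic: the probability that a random
#' deleterious site outscores a random neutral one, counting ties as 1/2.
#' The reported operating point maximizes Youden's J
#' (sensitivity + specificity - 1).
#'
#' @param scores Numeric score vector (higher = more deleterious).
#' @param labels Binary labels (1 = deleterious, 0 = neutral), same length.
#' @return An object of class `eval_result`: a list with `roc` (tibble of
#'   `threshold`, `fpr`, `tpr`), `auc`, `sensitivity`, `specificity`,
#'   `threshold`, `n_pos`, `n_neg`. Use [tidy()] for the curve and
#'   [glance()] for the scalar summary.
#' @export
#' @examples
#' roc_auc(c(.9, .8, .2, .1), c(1, 1, 0, 0))$auc # 1
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_hotspotr("`scores` and `labels` differ in length.",
                  "hotspotr_validation_error")
  }
  if (anyNA(scores) || anyNA(labels) || any(!is.finite(scores))) {
    stop_hotspotr("Scores and labels must be finite and non-missing.",
                  "hotspotr_validation_error")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    stop_hotspotr("Labels must contain both classes (0 and 1).",
                  "hotspotr_validation_error")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores so ties advance TPR and FPR jointly (diagonal segment)
  last_of_group <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1L - y)[last_of_group]
  roc <- tibble(
    threshold = c(Inf, s[last_of_group]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  j <- roc$tpr - roc$fpr
  best <- which.max(j)
  structure(
    list(
      roc = roc,
      auc = auc,
      sensitivity = roc$tpr[best],
      specificity = 1 - roc$fpr[best],
      threshold = roc$threshold[best],
      n_pos = n_pos,
      n_neg = n_neg
    ),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> AUC = %.4f (sens %.3f / spec %.3f at threshold %.4g; %d+/%d-)\n",
              x$auc, x$sensitivity, x$specificity, x$threshold, x$n_pos, x$n_neg))
  invisible(x)
}

#' @describeIn roc_auc Tidy the ROC curve points into a tibble.
#' @param x An `eval_result`.
#' @param ... Unused.
#' @export
tidy.eval_result <- function(x, ...) x$roc

#' @describeIn roc_auc One-row tibble with `auc`, `sensitivity`,
#'   `specificity`, `threshold`, `n_pos`, `n_neg`.
#' @export
glance.eval_result <- function(x, ...) {
  tibble(auc = x$auc, sensitivity = x$sensitivity,
         specificity = x$specificity, threshold = x$threshold,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Evaluate every feature column of a site table as a single score
#'
#' The single-score analogue of the combined-classifier evaluation: each
#' feature column is used directly as the ranking score.
#'
#' @param table A feature table with a `label` column.
#' @return A tibble with one row per feature: `feature`, `auc`,
#'   `sensitivity`, `specificity`.
#' @export
evaluate_single_scores <- function(table) {
  feats <- feature_names(table)
  purrr::map(feats, function(f) {
    ev <- roc_auc(table[[f]], table$label)
    dplyr::bind_cols(tibble(feature = f), glance(ev)[c("auc", "sensitivity", "specificity")])
  }) |> purrr::list_rbind()
}

#' Write an evaluation report (ROC points TSV + summary JSON)
#'
#' @param result An `eval_result`.
#' @param prefix Output path prefix; writes `<prefix>_roc.tsv` and
#'   `<prefix>_metrics.json`.
#' @param extra Named list merged into the JSON summary (e.g. scheme name).
#' @return Invisibly, the two paths.
#' @export
write_eval_result <- function(result, prefix, extra = list()) {
  stopifnot(inherits(result, "eval_result"))
  roc_path <- paste0(prefix, "_roc.tsv")
  json_path <- paste0(prefix, "_metrics.json")
  readr::write_tsv(result$roc, roc_path)
  payload <- c(list(auc = result$auc, sensitivity = result$sensitivity,
                    specificity = result$specificity,
                    threshold = result$threshold), extra)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(roc = roc_path, metrics = json_path))
}
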