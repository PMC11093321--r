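#' Plot a contact map as a probability heatmap
#'
#' @param object A [contact_map()].
#' @param min_p Hide pairs below this probability (default 0.1, which keeps
#'   the plot readable for fuzzy predictor maps).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_map <- function(object, min_p = 0.1, ...) {
  df <- tidy(object) |> dplyr::filter(.data$p >= min_p)
  df <- dplyr::bind_rows(df, dplyr::rename(df, i = "j", j = "i"))
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "P(contact)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s [%s]", object$protein_id, object$source_tag),
      x = "residue", y = "residue"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object An `eval_result` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166AC", linewidth = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "False-positive rate (1 - specificity)",
      y = "True-positive rate (sensitivity)",
      title = sprintf("ROC, AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-residue score profiles along the sequence
#'
#' @param scores A long score tibble from [score_protein()].
#' @param which_scores Score names to show (default `"W3"`, the strongest
#'   single predictor family).
#' @param use_percentile Plot percentile-normalized values instead of raw.
#' @return A ggplot object faceted by score and source.
#' @export
plot_score_profile <- function(scores, which_scores = "W3",
                               use_percentile = TRUE) {
  df <- dplyr::filter(as_tibble(scores), .data$score %in% which_scores)
  val <- if (use_percentile) "percentile" else "raw"
  ggplot2::ggplot(df, ggplot2::aes(.data$residue, .data[[val]],
                                   colour = .data$source)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_grid(score ~ protein_id, scales = "free") +
    ggplot2::labs(x = "residue position", y = val) +
    ggplot2::theme_minimal()
}
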