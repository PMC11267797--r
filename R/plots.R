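## ggplot2 displays for score results and evaluation curves.

#' Plot per-atom score attributions
#'
#' Bar chart of each atom's (non-positive) contribution: the more negative
#' the bar, the rarer the fragment centred on that atom is in the
#' building-block and reaction-centre corpora — the plot analogue of
#' darker-is-harder atom highlighting on a depiction.
#'
#' @param object An `sa_score`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sa_score <- function(object, ...) {
  dat <- atom_contributions(object)
  dat$atom_label <- sprintf("%s%d", dat$element, dat$atom)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$atom_label, .data$atom),
    y = .data$contribution, fill = .data$contribution
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_gradient(low = "#67000d", high = "#fee0d2") +
    ggplot2::labs(
      x = "atom", y = "fragment score contribution",
      title = sprintf(
        "%s  (score %.2f)", write_smiles(object$molecule), object$normalized
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot ROC and precision-recall curves for labeled scores
#'
#' @param data Data frame with score and label columns (see
#'   [evaluate_scores()]).
#' @param score_col,label_col,positive As in [evaluate_scores()].
#' @return A ggplot with one panel per curve type.
#' @export
plot_evaluation <- function(data, score_col = "score", label_col = "label",
                            positive = "HS") {
  roc <- roc_curve(data, score_col, label_col, positive)
  pr <- pr_curve(data, score_col, label_col, positive)
  curves <- dplyr::bind_rows(
    tibble::tibble(x = roc$fpr, y = roc$tpr, panel = "ROC"),
    tibble::tibble(x = c(0, pr$recall), y = c(pr$precision[1], pr$precision),
                   panel = "Precision-recall")
  )
  auc <- evaluate_scores(data, score_col, label_col, positive)
  labs <- tibble::tibble(
    panel = c("ROC", "Precision-recall"),
    text = sprintf("AUC = %.3f", c(auc$roc_auc, auc$pr_auc))
  )
  ggplot2::ggplot(curves, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::geom_text(
      data = labs, ggplot2::aes(label = .data$text), x = 0.7, y = 0.1,
      inherit.aes = FALSE
    ) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "FPR / recall", y = "TPR / precision") +
    ggplot2::theme_minimal()
}
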