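# ggplot2 autoplot methods for the result objects.

#' Plot a ROC curve from a metrics report
#'
#' @param object A `"metrics_report"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %s)", fmt3(object$auc))) +
    ggplot2::theme_minimal()
}

#' Plot cross-validated accuracy by split
#'
#' One box per train-test split (facetted by architecture when several
#' were run), showing the spread over training repetitions.
#'
#' @param object A `"cv_result"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$results,
                       ggplot2::aes(x = factor(.data$split), y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = "Train-test split", y = "Test accuracy") +
    ggplot2::theme_minimal()
  if (length(object$architectures) > 1L) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$architecture))
  }
  p
}

#' Plot leave-one-out rule ablation deltas
#'
#' Horizontal bars of the accuracy change when each rule is invalidated;
#' zero-impact rules are omitted (they are listed in the report).
#'
#' @param object An `"ablation_report"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ablation_report
#' @export
autoplot.ablation_report <- function(object, ...) {
  d <- object$deltas[object$deltas$delta != 0, , drop = FALSE]
  d <- d[order(d$delta), ]
  d$rule <- factor(d$rule, levels = d$rule)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta, y = .data$rule)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "Accuracy change when rule invalidated", y = NULL,
                  title = sprintf("Baseline accuracy %.3f",
                                  object$baseline_accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot the saliency-frequency map
#'
#' Frequency bars of the most recurrently salient words, one panel per
#' ground-truth class.
#'
#' @param object A `"saliency_report"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot saliency_report
#' @export
autoplot.saliency_report <- function(object, ...) {
  d <- object$top |>
    group_by(.data$class) |>
    arrange(.data$n, .by_group = TRUE) |>
    ungroup()
  d$word <- paste(d$class, d$word, sep = "_")
  d$word <- factor(d$word, levels = unique(d$word))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$word)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$class), scales = "free_y") +
    ggplot2::scale_y_discrete(labels = function(l) sub("^[^_]*_", "", l)) +
    ggplot2::labs(x = "Records in which word is among the most salient",
                  y = NULL) +
    ggplot2::theme_minimal()
}
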