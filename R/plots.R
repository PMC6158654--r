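#' Plot a 2-D embedding
#'
#' Scatter plot of the t-SNE coordinates, coloured by label when one is
#' supplied and shaped by the train/validation partition.
#'
#' @param embedding An `aodeep_embedding` tibble.
#' @param labels Optional tibble with `id` and `label` (1 = antioxidant).
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, labels = NULL) {
  df <- embedding
  if (!is.null(labels)) {
    df <- dplyr::left_join(df, labels[, c("id", "label")], by = "id")
    df$class <- factor(ifelse(df$label == 1, "antioxidant", "non-antioxidant"))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
  if (!is.null(labels))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$class,
                                              shape = .data$partition),
                                 alpha = 0.8)
  else
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$partition), alpha = 0.8)
  p
}

#' @rdname plot_embedding
#' @param object An `aodeep_embedding`.
#' @param ... Passed to [plot_embedding()].
#' @export
autoplot.aodeep_embedding <- function(object, ...) plot_embedding(object, ...)

#' Plot training-loss histories
#'
#' Per-epoch weighted losses of the two training phases: reconstruction
#' error during pre-training, binary cross-entropy during fine-tuning.
#'
#' @param object An `aodeep_feature_learner`.
#' @param ... Unused.
#' @return A ggplot object faceted by phase.
#' @export
autoplot.aodeep_feature_learner <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~phase, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = "Weighted loss") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object An `aodeep_cv`.
#' @param ... Unused.
#' @return A ggplot object: one panel per metric, folds on the x axis, the
#'   pooled value as a dashed reference line.
#' @export
autoplot.aodeep_cv <- function(object, ...) {
  metrics <- c("Sn", "Sp", "Acc", "precision", "F1", "MCC")
  per_fold <- tidyr::pivot_longer(object$per_fold[, c("fold", metrics)],
                                  -"fold", names_to = "metric")
  pooled <- tidyr::pivot_longer(object$pooled[, metrics],
                                dplyr::everything(), names_to = "metric")
  ggplot2::ggplot(per_fold, ggplot2::aes(x = .data$fold, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = pooled,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "Fold", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
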