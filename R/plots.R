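# ggplot2 visualisations for fitted models, attention maps and predictions.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the training history of a fitted model
#'
#' Training loss and validation AUROC/AUPRC per epoch.
#'
#' @param object A `ppis_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppis_model
#' @export
autoplot.ppis_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "value")
  h <- h[!is.na(h$value), ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Heatmap of a self-attention map
#'
#' @param attention Row-stochastic `N_v` x `N_v` attention matrix (e.g. the
#'   `"attention"` attribute of [forward()] or [muse_fuse()]).
#' @param labels Optional binary interface labels to mark along the axes.
#' @return A ggplot object.
#' @export
plot_attention_map <- function(attention, labels = NULL) {
  n <- nrow(attention)
  df <- expand.grid(query = seq_len(n), key = seq_len(n))
  df$weight <- as.vector(attention)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$key, y = .data$query,
                                        fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "key residue", y = "query residue",
                  title = "Self-attention weights") +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    pos <- which(labels > 0)
    p <- p + ggplot2::annotate("point", x = pos, y = rep(0, length(pos)),
                               shape = 17, colour = "red", size = 1.5)
  }
  p
}

#' Per-residue prediction profile
#'
#' Interface probability along the chain, with the threshold and (when
#' available) the true labels.
#'
#' @param predictions Tibble from [predict.ppis_model()].
#' @param threshold Classification threshold to draw (default 0.5).
#' @return A ggplot object.
#' @export
plot_predictions <- function(predictions, threshold = 0.5) {
  p <- ggplot2::ggplot(predictions,
                       ggplot2::aes(x = .data$residue_number,
                                    y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "residue", y = "interface probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if ("label" %in% names(predictions)) {
    p <- p + ggplot2::geom_point(
      data = predictions[predictions$label > 0, ],
      colour = "red", size = 1.2)
  }
  p
}
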