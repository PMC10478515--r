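# ggplot2 visualizations for the main result types.

#' Plot a speckle pattern
#'
#' @param data Pattern tibble.
#' @param i Row index of the pattern to show.
#' @param trans Intensity transform for display (`"log1p"` or
#'   `"identity"`).
#' @return A ggplot object.
#' @export
plot_pattern <- function(data, i = 1L, trans = c("log1p", "identity")) {
  trans <- match.arg(trans)
  img <- data$image[[i]]
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$intensity <- as.vector(t(img))  # expand_grid varies col fastest
  if (trans == "log1p") df$intensity <- log1p(pmax(df$intensity, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = if (trans == "log1p") {
      "log(1 + I)"
    } else "I") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(data$label[i], " (", data$sample_id[i], ")"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Training-history curves
#'
#' @param object A `speckle_fit`.
#' @param ... Unused.
#' @return A ggplot of training and validation triplet loss per epoch.
#' @export
autoplot.speckle_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history[, c("epoch", "train_loss",
                                              "val_loss")],
                           -"epoch", names_to = "set", values_to = "loss")
  h$set <- sub("_loss", "", h$set)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "mean triplet loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' Fluence-scan curves
#'
#' @param object A tibble returned by [fluence_scan()].
#' @param metric `"accuracy"` or `"macro_f1"`.
#' @param ... Unused.
#' @return A ggplot of the metric against the fluence scaling factor, one
#'   curve per few-shot scenario.
#' @export
autoplot.speckle_fluence_scan <- function(object,
                                          metric = c("accuracy", "macro_f1"),
                                          ...) {
  metric <- match.arg(metric)
  df <- as.data.frame(object)
  df$shots <- factor(df$shots)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fluence_factor,
                                   y = .data[[metric]],
                                   color = .data$shots)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "fluence scaling factor", y = metric,
                  color = "shots") +
    ggplot2::theme_minimal()
}

#' Embedding map
#'
#' Scatter plot of a 2-D projection (e.g. from [tsne_export()]).
#'
#' @param proj Tibble with `x`, `y`, `label`.
#' @return A ggplot object.
#' @export
plot_embedding_map <- function(proj) {
  ggplot2::ggplot(proj, ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = NULL, y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
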