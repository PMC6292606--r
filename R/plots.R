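#' Plot a darkfield image with detections
#'
#' Renders the image as a raster and overlays detection bounding boxes,
#' and optionally ground-truth object boxes for visual comparison.
#'
#' @param image a [ctc_image].
#' @param objects a `ctc_objects` tibble of detections (optional).
#' @param gt_objects a `ctc_objects` tibble of ground-truth objects
#'   (optional).
#' @return A ggplot object.
#' @export
plot_detections <- function(image, objects = NULL, gt_objects = NULL) {
  px <- image$pixels / 255
  rgb_vec <- grDevices::rgb(px[, , 1], px[, , 2], px[, , 3])
  df <- tidyr::expand_grid(row = seq_len(image$height) - 1L,
                           col = seq_len(image$width) - 1L)
  df$fill <- rgb_vec[(df$col) * image$height + df$row + 1L]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  box_layer <- function(obj, color) {
    ggplot2::geom_rect(
      data = tibble::as_tibble(obj),
      ggplot2::aes(xmin = .data$bbox_min_col - 0.5,
                   xmax = .data$bbox_max_col - 0.5,
                   ymin = .data$bbox_min_row - 0.5,
                   ymax = .data$bbox_max_row - 0.5),
      inherit.aes = FALSE, fill = NA, color = color, linewidth = 0.6
    )
  }
  if (!is.null(gt_objects) && nrow(gt_objects)) {
    p <- p + box_layer(gt_objects, "yellow")
  }
  if (!is.null(objects) && nrow(objects)) {
    p <- p + box_layer(objects, "green")
  }
  p
}

#' Plot an ensemble score grid
#'
#' @param scores numeric score matrix from [predict_scores()].
#' @return A ggplot heat map (warmer = more CTC-like).
#' @export
plot_scores <- function(scores) {
  df <- tidyr::expand_grid(row = seq_len(nrow(scores)) - 1L,
                           col = seq_len(ncol(scores)) - 1L)
  df$score <- scores[(df$col) * nrow(scores) + df$row + 1L]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Training-error bound curve of a boost model
#'
#' Shows the per-round weighted stump error and the cumulative
#' exponential-loss bound on the training error.
#'
#' @param object a `ctc_boost`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ctc_boost <- function(object, ...) {
  st <- object$stumps
  df <- tidyr::pivot_longer(st[, c("round", "error", "bound")],
                            c("error", "bound"),
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$round, .data$value,
                                   color = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "boosting round", y = NULL,
                  title = "Stump error and training-error bound") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
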