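#' Plot an image with its bounding boxes
#'
#' Renders the raster with predicted boxes (and optionally ground truth)
#' overlaid as rectangles, in pixel coordinates with the origin at the top
#' left as in the scan.
#'
#' @param image A [source_image].
#' @param boxes A boxes tibble (normalized coordinates).
#' @param truth Optional ground-truth tibble, drawn dashed.
#' @return A ggplot object.
#' @export
plot_boxes <- function(image, boxes = NULL, truth = NULL) {
  w <- img_width(image); h <- img_height(image)
  raster <- grDevices::as.raster(image$pixels / 255)
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(raster, xmin = 0, xmax = w, ymin = -h, ymax = 0) +
    ggplot2::scale_y_continuous(labels = function(v) -v) +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(-h, 0), expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)")
  if (!is.null(boxes) && nrow(boxes))
    p <- p + ggplot2::geom_rect(
      data = as_tibble(boxes),
      ggplot2::aes(xmin = .data$x0 * w, xmax = .data$x1 * w,
                   ymin = -.data$y1 * h, ymax = -.data$y0 * h),
      fill = NA, colour = "red", linewidth = 0.4)
  if (!is.null(truth) && nrow(truth))
    p <- p + ggplot2::geom_rect(
      data = as_tibble(truth),
      ggplot2::aes(xmin = .data$x0 * w, xmax = .data$x1 * w,
                   ymin = -.data$y1 * h, ymax = -.data$y0 * h),
      fill = NA, colour = "blue", linetype = "dashed", linewidth = 0.4)
  p
}

#' @export
autoplot.seg_eval <- function(object, ...) {
  counts <- tibble(outcome = factor(c("tp", "fp", "fn"), levels = c("tp", "fp", "fn")),
                   n = c(object$tp, object$fp, object$fn))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$outcome, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "boxes",
      title = sprintf("precision %.2f, recall %.2f (IoU ≥ %.2f)",
                      object$precision, object$recall, object$iou_threshold))
}
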