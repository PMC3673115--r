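# Visual diagnostics: raster overlays of detected spots and cluster
# rectangles, mirroring how CAD marks are reviewed.

#' Plot a mammogram with detection overlays
#'
#' Renders the display-domain (ILT) image with accepted microcalcifications
#' as small squares, detected cluster rectangles in one color and
#' ground-truth rectangles in another.
#'
#' @param image A [mammogram()] (raw 14-bit images are ILT-transformed for
#'   display).
#' @param detection Optional `mcc_detection` (or a detections tibble).
#' @param truth Optional [ground_truth()].
#' @return A ggplot object.
#' @export
plot_detections <- function(image, detection = NULL, truth = NULL) {
  img <- if (inherits(image, "mammogram") && image$bit_depth == 14L) {
    ilt_transform(image)
  } else {
    image
  }
  px <- as_pixel_matrix(img)
  df <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$value <- px[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  rect_layer <- function(rects, color) {
    ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = .data$col0, xmax = .data$col1,
                   ymin = .data$row0, ymax = .data$row1),
      inherit.aes = FALSE, fill = NA, color = color, linewidth = 0.4
    )
  }
  if (!is.null(detection)) {
    acc <- if (inherits(detection, "mcc_detection")) detection$accepted else NULL
    dets <- if (inherits(detection, "mcc_detection")) {
      detection$detections
    } else {
      detection
    }
    if (!is.null(acc) && nrow(acc)) {
      p <- p + ggplot2::geom_rect(
        data = acc,
        ggplot2::aes(xmin = .data$centroid_col - 3, xmax = .data$centroid_col + 3,
                     ymin = .data$centroid_row - 3, ymax = .data$centroid_row + 3),
        inherit.aes = FALSE, fill = NA, color = "yellow", linewidth = 0.3
      )
    }
    if (nrow(dets)) p <- p + rect_layer(dets, "red")
  }
  if (!is.null(truth) && nrow(truth$mcc_rects)) {
    p <- p + rect_layer(truth$mcc_rects, "cyan")
  }
  p
}
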