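# Sobel and Canny edge maps used by the candidate detector. Both return
# logical edge masks; the candidate stage fills closed contours, opens, and
# ORs the two results.

sobel_gradients <- function(x) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)  # d/dcol
  gx <- convolve2_reflect(x, sx)
  gy <- convolve2_reflect(x, t(sx))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Sobel edge map
#'
#' Gradient magnitude from the 3x3 Sobel operators, binarized at the
#' standard automatic threshold of four times the mean magnitude. This
#' self-normalizing rule adapts to how sparse the input is: on a
#' threshold-shifted image whose background is mostly zero the mean is
#' small and faint blob edges are kept, while on a dense image the
#' threshold rises and prevents the edge map from percolating into one
#' connected mass. (A fixed Otsu split of the long-tailed gradient
#' histogram would instead chase the few extreme bright-spot edges.)
#'
#' @param image Numeric matrix.
#' @return Logical matrix.
#' @export
sobel_edges <- function(image) {
  g <- sobel_gradients(as_pixel_matrix(image))
  m <- mean(g$mag)
  if (m == 0) return(matrix(FALSE, nrow(g$mag), ncol(g$mag)))
  g$mag >= 4 * m
}

gaussian_mask <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  d <- -r:r
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Canny edge map
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis: weak edge pixels
#' (`mag >= low * max`) are kept only when 8-connected to a strong pixel
#' (`mag >= high * max`).
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian smoothing scale (default 1).
#' @param low,high Hysteresis thresholds as fractions of the maximum gradient
#'   magnitude (defaults 0.1 and 0.2).
#' @return Logical matrix.
#' @export
canny_edges <- function(image, sigma = 1, low = 0.1, high = 0.2) {
  x <- as_pixel_matrix(image)
  xs <- convolve2_reflect(x, gaussian_mask(sigma))
  g <- sobel_gradients(xs)
  mag <- g$mag
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nrow(x), ncol(x)))
  # quantize gradient direction into 4 sectors and suppress non-maxima
  ang <- atan2(g$gy, g$gx)                  # gy = d/drow
  sector <- (round(ang / (pi / 4)) %% 4)    # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  nr <- nrow(mag); nc <- ncol(mag)
  shift2 <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  nms <- matrix(FALSE, nr, nc)
  for (s in 0:3) {
    o <- off[[s + 1]]
    n1 <- shift2(mag, o[1], o[2])
    n2 <- shift2(mag, -o[1], -o[2])
    nms <- nms | (sector == s & mag >= n1 & mag >= n2)
  }
  strong <- nms & mag >= high * mx
  weak <- nms & mag >= low * mx
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  lbl <- label_components(weak)
  keep <- unique(lbl[strong])
  keep <- keep[keep > 0L]
  matrix(lbl %in% keep, nr, nc)
}
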