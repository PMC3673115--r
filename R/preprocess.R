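#' Inverted logarithmic transform (14-bit raw to 12-bit display)
#'
#' Raw detector values are log-compressed and inverted so that strongly
#' attenuating tissue (low transmitted signal) appears bright, matching
#' clinical reading conditions, while the intensity resolution drops from 14
#' to 12 bits:
#' \deqn{t = \mathrm{round}\left(4095\,\Big(1 - \frac{\ln(1+r)}{\ln(1+16383)}\Big)\right)}
#' The mapping is monotone decreasing with endpoints 0 -> 4095 and
#' 16383 -> 0.
#'
#' @param raw A 14-bit [mammogram()].
#' @return A 12-bit [mammogram()].
#' @export
#' @examples
#' m <- mammogram(matrix(c(0, 16383), 1, 2), bit_depth = 14)
#' ilt_transform(m)$pixels   # 4095, 0
ilt_transform <- function(raw) {
  stopifnot(inherits(raw, "mammogram"))
  if (raw$bit_depth != 14L) {
    abort(sprintf("ilt_transform expects a 14-bit image, got %d-bit", raw$bit_depth))
  }
  t <- round(4095 * (1 - log1p(raw$pixels) / log(16384)))
  mammogram(t, bit_depth = 12L, pixel_spacing_mm = raw$pixel_spacing_mm)
}

# Real-valued inverse of the ILT curve: maps 12-bit display values back to
# the (unrounded) 14-bit raw scale. Used by the synthetic generator to encode
# a designed display-domain scene as raw data.
ilt_inverse <- function(t) {
  expm1((1 - t / 4095) * log(16384))
}

#' Otsu's threshold on an integer image
#'
#' Exhaustively scans every threshold of the gray-level histogram and returns
#' the one minimizing the within-class variance (equivalently, maximizing the
#' between-class variance). The returned `T` splits pixels into background
#' `x < T` and foreground `x >= T`.
#'
#' @param image A [mammogram()] or a non-negative integer matrix.
#' @return Integer threshold.
#' @export
otsu_threshold <- function(image) {
  x <- as_pixel_matrix(image)
  x <- as.vector(x)
  if (min(x) == max(x)) abort("Otsu threshold undefined for a constant image")
  lev <- 0:max(x)
  h <- tabulate(x + 1L, nbins = length(lev))
  p <- h / sum(h)
  # candidate thresholds T = 1..max: classes {< T}, {>= T}
  w0 <- cumsum(p)[-length(p)]            # P(x < T) for T = 1..max
  w1 <- 1 - w0
  m <- cumsum(p * lev)
  mu_t <- m[length(m)]
  m0 <- m[-length(m)]
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, length(w0))
  between[valid] <- (mu_t * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  which.max(between)                     # T in 1..max (ties -> smallest)
}

# Otsu on a real-valued image via 1024-bin quantization; returns a threshold
# on the original scale.
otsu_threshold_real <- function(x, bins = 1024L) {
  x <- as.vector(x)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) abort("Otsu threshold undefined for a constant image")
  q <- pmin(floor((x - lo) / (hi - lo) * bins), bins - 1L)
  tq <- otsu_threshold(matrix(as.integer(q), 1))
  lo + tq / bins * (hi - lo)
}

#' Breast-region mask from an ILT image
#'
#' Binarizes the display-domain image at its Otsu threshold (tissue is bright
#' after inversion), labels connected components (8-connectivity) and keeps
#' the single largest one as the breast region. Later pipeline stages restrict
#' all computation to this mask.
#'
#' @param ilt_image A 12-bit [mammogram()] (or matrix).
#' @return Logical matrix of the same shape, `TRUE` inside the breast.
#' @export
detect_breast_region <- function(ilt_image) {
  x <- as_pixel_matrix(ilt_image)
  t <- otsu_threshold(matrix(as.integer(round(x)), nrow(x)))
  fg <- x >= t
  if (!any(fg)) abort("empty foreground: no breast region found")
  lbl <- label_components(fg)
  sizes <- tabulate(lbl[lbl > 0L])
  lbl == which.max(sizes)
}
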