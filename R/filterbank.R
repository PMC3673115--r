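# The 18-image filter bank: the ILT image itself, its top-hat transform, a
# two-level wavelet high-pass reconstruction, and 15 Laws texture images.

#' Discrete disk structuring element
#'
#' Pixels `(dr, dc)` with `dr^2 + dc^2 <= r^2` in a `(2r+1) x (2r+1)` window.
#'
#' @param radius_px Integer radius (>= 1).
#' @return A 0/1 numeric matrix usable as an EBImage brush.
#' @export
disk_element <- function(radius_px = 7L) {
  stopifnot(radius_px >= 1)
  d <- -radius_px:radius_px
  k <- outer(d^2, d^2, "+") <= radius_px^2
  matrix(as.numeric(k), nrow = length(d))
}

#' White top-hat transform
#'
#' `P = I - opening(I, S)` where the opening is grayscale erosion followed by
#' dilation with a disk `S`. Peaks narrower than the disk survive; smooth
#' background is removed. `P` is non-negative and pointwise `<= I`
#' (anti-extensivity of the opening).
#'
#' @param image A [mammogram()] or numeric matrix.
#' @param radius_px Disk radius in pixels (default 7).
#' @return Numeric matrix of the same shape.
#' @export
tophat_filter <- function(image, radius_px = 7L) {
  x <- as_pixel_matrix(image)
  kern <- disk_element(radius_px)
  s <- max(x)
  if (s <= 0) return(matrix(0, nrow(x), ncol(x)))
  # reflect-pad so border behavior is well defined; EBImage grayscale
  # morphology operates on [0,1], and the opening is scale-equivariant
  p <- radius_px
  xp <- reflect_pad(x, p) / s
  opened <- EBImage::dilate(EBImage::erode(xp, kern), kern) * s
  opened <- opened[(p + 1):(p + nrow(x)), (p + 1):(p + ncol(x)), drop = FALSE]
  pmax(x - opened, 0)
}

#' Laws 5-tap kernels
#'
#' The five basic texture kernels: Level `L = (1,4,6,4,1)`,
#' Edge `E = (-1,-2,0,2,1)`, Spot `S = (-1,0,2,0,-1)`,
#' Wave `W = (-1,2,0,-2,1)`, Ripple `R = (1,-4,6,-4,1)`.
#'
#' @return Named list of numeric length-5 vectors.
#' @export
laws_kernels <- function() {
  list(
    L = c(1, 4, 6, 4, 1),
    E = c(-1, -2, 0, 2, 1),
    S = c(-1, 0, 2, 0, -1),
    W = c(-1, 2, 0, -2, 1),
    R = c(1, -4, 6, -4, 1)
  )
}

#' The 15 Laws mask names used by the filter bank
#' @return Character vector of length 15.
#' @export
laws_names <- function() {
  c("LL", "EE", "SS", "RR", "WW", "LE", "LS", "LR", "LW",
    "ES", "ER", "EW", "SR", "SW", "RW")
}

#' 5x5 Laws mask from a two-letter name
#'
#' The mask is the outer product of the first-letter kernel and the
#' second-letter kernel, e.g. `laws_mask("LE") == outer(L, E)`.
#'
#' @param name Two letters from `{L, E, S, W, R}`.
#' @return A 5x5 numeric matrix.
#' @export
laws_mask <- function(name) {
  k <- laws_kernels()
  a <- substr(name, 1, 1); b <- substr(name, 2, 2)
  if (!a %in% names(k) || !b %in% names(k)) {
    abort(sprintf("unknown Laws mask '%s'", name))
  }
  outer(k[[a]], k[[b]])
}

# 2-D convolution with reflect padding and "same" output size.
convolve2_reflect <- function(x, mask) {
  p <- (dim(mask) - 1) %/% 2
  xp <- reflect_pad(x, p[1], p[2])
  out <- EBImage::filter2(xp, mask, boundary = 0)
  out[(p[1] + 1):(p[1] + nrow(x)), (p[2] + 1):(p[2] + ncol(x)), drop = FALSE]
}

#' Apply the 15 Laws filters
#'
#' Convolves the image with each of the 15 outer-product masks
#' (reflect-padded, same-size output).
#'
#' @param image A [mammogram()] or numeric matrix.
#' @return Named list of 15 numeric matrices.
#' @export
laws_filter_bank <- function(image) {
  x <- as_pixel_matrix(image)
  out <- lapply(laws_names(), function(nm) convolve2_reflect(x, laws_mask(nm)))
  names(out) <- laws_names()
  out
}

#' Feature-image names, in canonical order
#' @return Character vector of length 18.
#' @export
feature_image_names <- function() c("ILT", "TopHat", "Wavelet", laws_names())

#' Build the 18 feature images from an ILT mammogram
#'
#' The set comprises the ILT image itself, its top-hat transform, the wavelet
#' high-pass reconstruction, and the 15 Laws images. All share the input's
#' shape.
#'
#' @param ilt A 12-bit [mammogram()] (or numeric matrix).
#' @param tophat_radius_px Disk radius for the top-hat transform.
#' @return Named list of 18 numeric matrices, class `feature_images`.
#' @export
build_feature_images <- function(ilt, tophat_radius_px = 7L) {
  x <- as_pixel_matrix(ilt)
  out <- c(
    list(
      ILT = x * 1.0,
      TopHat = tophat_filter(x, tophat_radius_px),
      Wavelet = wavelet_highpass(x)
    ),
    laws_filter_bank(x)
  )
  stopifnot(identical(names(out), feature_image_names()))
  structure(out, class = "feature_images")
}

#' @export
print.feature_images <- function(x, ...) {
  cat(sprintf("<feature_images> 18 images, %d x %d\n",
              nrow(x[[1]]), ncol(x[[1]])))
  invisible(x)
}
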