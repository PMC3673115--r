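# GLCM texture features: a 16 x 16 window around each candidate is quantized
# to `levels` gray levels, co-occurrence matrices are built for offsets d = 1
# at 0/45/90/135 degrees (symmetric counting), and 14 Haralick-style
# statistics are computed per matrix, giving 56 values per feature image.
#
# The per-window R path below is the reference implementation; the batch
# extractor used by the pipeline is compiled (src/glcm.cpp) and is tested
# against this path.

#' The 14 GLCM feature names, in canonical order
#' @return Character vector of length 14.
#' @export
haralick_feature_names <- function() {
  c("contrast", "homogeneity", "energy", "correlation", "shade",
    "prominence", "idm", "entropy", "intensity", "variance",
    "sum_average", "sum_entropy", "diff_entropy", "diff_variance")
}

#' The GLCM offset angles in degrees
#' @return Integer vector `c(0, 45, 90, 135)`.
#' @export
glcm_angles <- function() c(0L, 45L, 90L, 135L)

# Column names of a 56-value feature vector, feature-major:
# contrast_0, contrast_45, ..., diff_variance_135.
feature_vector_names <- function() {
  as.vector(t(outer(haralick_feature_names(), glcm_angles(), paste, sep = "_")))
}

#' Extract a square window centred on a pixel
#'
#' For window size `2h` the window covers rows `(r-h)..(r+h-1)` and columns
#' `(c-h)..(c+h-1)`; out-of-bounds positions are filled by reflection, so the
#' window is defined at every interior or border centre.
#'
#' @param image Numeric matrix.
#' @param center Length-2 vector `(row, col)`; rounded to the nearest pixel.
#' @param size Even window side (default 16).
#' @return `size x size` numeric matrix.
#' @export
extract_window <- function(image, center, size = 16L) {
  stopifnot(size %% 2 == 0)
  x <- as_pixel_matrix(image)
  r <- round(center[1]); c <- round(center[2])
  stopifnot(r >= 1, r <= nrow(x), c >= 1, c <= ncol(x))
  h <- size %/% 2
  ridx <- reflect_clip(r - h + 0:(size - 1), nrow(x))
  cidx <- reflect_clip(c - h + 0:(size - 1), ncol(x))
  x[ridx, cidx, drop = FALSE]
}

# Reflect out-of-range 1-based indices back into 1..n.
reflect_clip <- function(idx, n) {
  idx <- abs(idx - 1L)                # reflect about 0 (half-sample at 0.5)
  period <- 2L * n
  idx <- idx %% period
  idx <- ifelse(idx >= n, period - 1L - idx, idx)
  idx + 1L
}

#' Quantize a window to a fixed number of gray levels
#'
#' Linear min-max rescaling of the window's own range onto levels
#' `0..levels-1`; a constant window maps entirely to level 0.
#'
#' @param patch Numeric matrix.
#' @param levels Number of gray levels.
#' @return Integer matrix with values in `0..levels-1`.
#' @export
quantize_patch <- function(patch, levels = 64L) {
  lo <- min(patch); hi <- max(patch)
  if (hi <= lo) return(matrix(0L, nrow(patch), ncol(patch)))
  q <- floor((patch - lo) / (hi - lo) * levels)
  matrix(as.integer(pmin(q, levels - 1L)), nrow(patch))
}

glcm_offset <- function(theta, d = 1L) {
  switch(as.character(theta),
         "0" = c(0L, d),
         "45" = c(-d, d),
         "90" = c(-d, 0L),
         "135" = c(-d, -d),
         abort(sprintf("unsupported GLCM angle %s", theta)))
}

#' Gray-level co-occurrence matrix
#'
#' Counts pixel pairs separated by the offset for angle `theta` at distance
#' `d`, in both directions (the matrix is symmetric), and normalizes so the
#' entries sum to 1. Row/column index `k` corresponds to gray level `k - 1`.
#'
#' @param patch Integer matrix of gray levels `0..levels-1` (e.g. from
#'   [quantize_patch()]).
#' @param theta Angle in degrees: 0, 45, 90 or 135.
#' @param d Offset distance (default 1).
#' @param levels Number of gray levels.
#' @return `levels x levels` numeric matrix with unit sum, class `glcm`.
#' @export
compute_glcm <- function(patch, theta, d = 1L, levels = 64L) {
  if (length(patch) == 0) abort("empty patch")
  stopifnot(all(patch >= 0), all(patch < levels))
  off <- glcm_offset(theta, d)
  nr <- nrow(patch); nc <- ncol(patch)
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  r2 <- r1 + off[1]; c2 <- c1 + off[2]
  rok <- r2 >= 1 & r2 <= nr; cok <- c2 >= 1 & c2 <= nc
  a <- patch[r1[rok], c1[cok], drop = FALSE]
  b <- patch[r2[rok], c2[cok], drop = FALSE]
  counts <- matrix(0, levels, levels)
  if (length(a)) {
    idx <- tabulate(a * levels + b + 1L, nbins = levels * levels)
    counts <- matrix(idx, levels, levels, byrow = TRUE)
    counts <- counts + t(counts)        # symmetric counting
  }
  s <- sum(counts)
  if (s == 0) abort("patch too small for the requested offset")
  structure(counts / s, class = c("glcm", "matrix"),
            theta = theta, d = d, levels = levels)
}

#' The 14 Haralick-style statistics of a normalized GLCM
#'
#' Given a normalized symmetric GLCM `P` over gray levels `i, j = 0..G-1`
#' with marginal mean `mu` and variance `var`:
#' contrast `sum (i-j)^2 P`; homogeneity `sum P/(1+|i-j|)`; energy
#' `sum P^2`; correlation `(sum ij P - mu^2)/var` (0 when `var = 0`);
#' cluster shade `sum (i+j-2mu)^3 P`; cluster prominence
#' `sum (i+j-2mu)^4 P`; inverse difference moment `sum P/(1+(i-j)^2)`;
#' entropy `-sum P log P`; intensity (GLCM mean) `mu`; sum-of-squares
#' variance `var`; sum average, sum entropy over the diagonal-sum
#' distribution `p_{x+y}`; difference entropy and difference variance over
#' the absolute-difference distribution `p_{x-y}`. Logarithms are natural
#' with the `0 log 0 = 0` convention.
#'
#' @param g A normalized GLCM matrix (entries sum to 1).
#' @return Named numeric vector of length 14 in [haralick_feature_names()]
#'   order.
#' @export
haralick_features <- function(g) {
  p <- unclass(g)
  n <- nrow(p)
  lev <- 0:(n - 1)
  px <- rowSums(p)
  mu <- sum(lev * px)
  va <- sum((lev - mu)^2 * px)
  i <- matrix(lev, n, n)
  j <- t(i)
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  # diagonal-sum distribution p_{x+y}(k), k = 0..2n-2
  k_sum <- as.vector(i + j)
  psum <- vapply(0:(2 * n - 2), function(k) sum(p[k_sum == k]), numeric(1))
  ks <- 0:(2 * n - 2)
  # absolute-difference distribution p_{x-y}(k), k = 0..n-1
  k_diff <- as.vector(abs(i - j))
  pdiff <- vapply(0:(n - 1), function(k) sum(p[k_diff == k]), numeric(1))
  kd <- 0:(n - 1)
  mu_d <- sum(kd * pdiff)
  out <- c(
    contrast = sum((i - j)^2 * p),
    homogeneity = sum(p / (1 + abs(i - j))),
    energy = sum(p^2),
    correlation = if (va > 0) (sum(i * j * p) - mu^2) / va else 0,
    shade = sum((i + j - 2 * mu)^3 * p),
    prominence = sum((i + j - 2 * mu)^4 * p),
    idm = sum(p / (1 + (i - j)^2)),
    entropy = -sum(xlogx(p)),
    intensity = mu,
    variance = va,
    sum_average = sum(ks * psum),
    sum_entropy = -sum(xlogx(psum)),
    diff_entropy = -sum(xlogx(pdiff)),
    diff_variance = sum((kd - mu_d)^2 * pdiff)
  )
  names(out) <- haralick_feature_names()
  out
}

#' 56-value texture vector for one window of one feature image
#'
#' Quantizes the window and concatenates the 14 features over the four
#' angles, feature-major (`contrast_0, contrast_45, ..., diff_variance_135`).
#'
#' @param image Numeric matrix (one feature image).
#' @param center Candidate centroid `(row, col)`.
#' @param size Window side (default 16).
#' @param levels GLCM gray levels (default 64).
#' @return Named numeric vector of length 56.
#' @export
texture_vector <- function(image, center, size = 16L, levels = 64L) {
  q <- quantize_patch(extract_window(image, center, size), levels)
  vals <- sapply(glcm_angles(), function(th) {
    haralick_features(compute_glcm(q, th, d = 1L, levels = levels))
  })
  out <- as.vector(t(vals))             # feature-major
  names(out) <- feature_vector_names()
  out
}

#' Texture vectors for one candidate across all 18 feature images
#'
#' @param feature_images A [build_feature_images()] result.
#' @param candidate One-row candidate tibble (or list with `centroid_row`,
#'   `centroid_col`).
#' @param size,levels Window side and GLCM gray levels.
#' @return Named list of 18 length-56 numeric vectors.
#' @export
extract_features <- function(feature_images, candidate, size = 16L, levels = 64L) {
  ctr <- c(candidate$centroid_row[1], candidate$centroid_col[1])
  lapply(feature_images, texture_vector, center = ctr, size = size,
         levels = levels)
}

#' Batch feature matrices for a candidate table
#'
#' Computes the 56-value texture vector of every candidate for each of the 18
#' feature images using the compiled extractor. Row order follows the
#' candidate table.
#'
#' @param feature_images A [build_feature_images()] result.
#' @param candidates Candidate tibble with `id`, `centroid_row`,
#'   `centroid_col` (and optionally `label`).
#' @param size,levels Window side and GLCM gray levels.
#' @return Named list (class `feature_matrices`) of 18 tibbles, each with
#'   `candidate_id`, the 56 feature columns, and `label` when present in the
#'   input.
#' @export
extract_feature_matrix <- function(feature_images, candidates,
                                   size = 16L, levels = 64L) {
  n <- nrow(candidates)
  rows <- as.integer(round(candidates$centroid_row))
  cols <- as.integer(round(candidates$centroid_col))
  out <- lapply(feature_images, function(img) {
    m <- if (n == 0) {
      matrix(numeric(), 0, 56)
    } else {
      glcm_features_batch(img, rows, cols, as.integer(size), as.integer(levels))
    }
    colnames(m) <- feature_vector_names()
    tb <- as_tibble(m)
    tb$candidate_id <- candidates$id
    if ("label" %in% names(candidates)) tb$label <- candidates$label
    tb[, c("candidate_id", setdiff(names(tb), c("candidate_id", "label")),
           intersect("label", names(tb)))]
  })
  structure(out, class = "feature_matrices")
}

#' @export
print.feature_matrices <- function(x, ...) {
  cat(sprintf("<feature_matrices> 18 images x %d candidates x 56 features\n",
              nrow(x[[1]])))
  invisible(x)
}
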