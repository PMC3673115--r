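# Two-level separable Daubechies-4 wavelet decomposition with removal of the
# level-2 approximation band. The orthogonal periodized pyramid transform is
# applied to a reflect-padded copy of the image (padded to a multiple of 4),
# which keeps perfect reconstruction exact while avoiding wrap-around content
# near the breast border; the result is cropped back to the input size.

# Daubechies-4 analysis low-pass taps.
daub4_taps <- function() {
  s3 <- sqrt(3)
  c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
}

# N x N orthogonal one-level periodized DAUB4 analysis matrix: the first N/2
# rows compute the approximation, the last N/2 the detail. N must be even.
daub4_matrix <- function(n) {
  stopifnot(n %% 2 == 0, n >= 4)
  h <- daub4_taps()
  g <- c(h[4], -h[3], h[2], -h[1])
  w <- matrix(0, n, n)
  for (k in 0:(n / 2 - 1)) {
    idx <- (2 * k + 0:3) %% n + 1
    w[k + 1, idx] <- w[k + 1, idx] + h
    w[n / 2 + k + 1, idx] <- w[n / 2 + k + 1, idx] + g
  }
  w
}

next_mult4 <- function(n) max(8L, as.integer(ceiling(n / 4) * 4))

#' Wavelet high-pass reconstruction (two-level DAUB4, LL2 removed)
#'
#' Performs a two-level separable 2-D discrete wavelet transform with the
#' Daubechies four-coefficient filter (only the level-1 approximation band is
#' decomposed further, the Mallat pyramid), zeroes the level-2 approximation
#' sub-band (LL2), and reconstructs. The output retains the spot-like
#' high-frequency structure of microcalcifications while the smooth
#' low-frequency background (which lives in LL2) is removed; a constant image
#' maps to (numerically) zero.
#'
#' @param image A [mammogram()] or numeric matrix with at least 8 rows and
#'   columns.
#' @return Numeric matrix of the input's shape.
#' @export
wavelet_highpass <- function(image) {
  x <- as_pixel_matrix(image) * 1.0
  if (nrow(x) < 8 || ncol(x) < 8) {
    abort("image smaller than the wavelet filter support (need >= 8 x 8)")
  }
  d <- wavelet_decompose2(x)
  d$coef[seq_len(d$nr / 4), seq_len(d$nc / 4)] <- 0   # kill LL2
  wavelet_reconstruct2(d)[seq_len(nrow(x)), seq_len(ncol(x)), drop = FALSE]
}

# Forward two-level transform on the reflect-padded image. Returns the packed
# coefficient matrix (standard pyramid layout) plus the padded dimensions.
wavelet_decompose2 <- function(x) {
  nr <- next_mult4(nrow(x)); nc <- next_mult4(ncol(x))
  xp <- x[reflect_index_to(nrow(x), nr), reflect_index_to(ncol(x), nc), drop = FALSE]
  wr1 <- daub4_matrix(nr); wc1 <- daub4_matrix(nc)
  a <- wr1 %*% xp %*% t(wc1)
  wr2 <- daub4_matrix(nr / 2); wc2 <- daub4_matrix(nc / 2)
  ll1 <- a[seq_len(nr / 2), seq_len(nc / 2)]
  a[seq_len(nr / 2), seq_len(nc / 2)] <- wr2 %*% ll1 %*% t(wc2)
  list(coef = a, nr = nr, nc = nc,
       wr1 = wr1, wc1 = wc1, wr2 = wr2, wc2 = wc2)
}

wavelet_reconstruct2 <- function(d) {
  a <- d$coef
  ll1 <- t(d$wr2) %*% a[seq_len(d$nr / 2), seq_len(d$nc / 2)] %*% d$wc2
  a[seq_len(d$nr / 2), seq_len(d$nc / 2)] <- ll1
  t(d$wr1) %*% a %*% d$wc1
}

# Extend 1..n to length m >= n by reflection.
reflect_index_to <- function(n, m) {
  idx <- seq_len(n)
  while (length(idx) < m) idx <- c(idx, rev(idx))
  idx[seq_len(m)]
}
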