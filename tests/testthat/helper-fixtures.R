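# Shared fixtures built in code.

# Small deterministic 14-bit raster with a bright blob on a gradient.
fixture_raw_image <- function(n = 48, seed = 42) {
  withr::with_seed(seed, {
    base <- outer(seq(2000, 9000, length.out = n),
                  seq(0, 3000, length.out = n), "+")
    px <- round(base + matrix(rnorm(n * n, sd = 50), n, n))
    px[20:24, 20:24] <- px[20:24, 20:24] + 3000
    mammogram(pmin(pmax(px, 0), 16383), bit_depth = 14)
  })
}

# Candidate tibble row built from an explicit pixel coordinate set.
make_candidate <- function(rows, cols, id = 1L) {
  tibble::tibble(
    id = id, area = length(rows),
    row0 = min(rows), row1 = max(rows), col0 = min(cols), col1 = max(cols),
    delta_x = max(cols) - min(cols) + 1L,
    delta_y = max(rows) - min(rows) + 1L,
    centroid_row = mean(rows), centroid_col = mean(cols)
  )
}

# Filled-rectangle candidate: height x width block at (r0, c0).
rect_candidate <- function(r0, c0, height, width, id = 1L) {
  cells <- expand.grid(r = r0:(r0 + height - 1), c = c0:(c0 + width - 1))
  make_candidate(cells$r, cells$c, id = id)
}

# Small cached synthetic phantom shared by slow tests.
cached_phantom <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_mammogram(synthetic_spec())
    val
  }
})

# Nested-loop GLCM oracle: symmetric pair counting at the given offset.
glcm_oracle <- function(patch, drow, dcol, levels) {
  counts <- matrix(0, levels, levels)
  nr <- nrow(patch); nc <- ncol(patch)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + drow; c2 <- c + dcol
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        i <- patch[r, c] + 1L; j <- patch[r2, c2] + 1L
        counts[i, j] <- counts[i, j] + 1
        counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  counts / sum(counts)
}

# Independent double-sum implementation of the 14 GLCM statistics.
haralick_oracle <- function(p) {
  g <- nrow(p)
  out <- numeric(14)
  px <- rowSums(p)
  mu <- sum((0:(g - 1)) * px)
  va <- sum(((0:(g - 1)) - mu)^2 * px)
  psum <- numeric(2 * g - 1)
  pdiff <- numeric(g)
  for (i in 0:(g - 1)) for (j in 0:(g - 1)) {
    pr <- p[i + 1, j + 1]
    out[1] <- out[1] + (i - j)^2 * pr
    out[2] <- out[2] + pr / (1 + abs(i - j))
    out[3] <- out[3] + pr^2
    out[5] <- out[5] + (i + j - 2 * mu)^3 * pr
    out[6] <- out[6] + (i + j - 2 * mu)^4 * pr
    out[7] <- out[7] + pr / (1 + (i - j)^2)
    if (pr > 0) out[8] <- out[8] - pr * log(pr)
    psum[i + j + 1] <- psum[i + j + 1] + pr
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + pr
  }
  corr <- 0
  if (va > 0) {
    for (i in 0:(g - 1)) for (j in 0:(g - 1)) {
      corr <- corr + i * j * p[i + 1, j + 1]
    }
    corr <- (corr - mu^2) / va
  }
  out[4] <- corr
  out[9] <- mu
  out[10] <- va
  for (k in 0:(2 * g - 2)) {
    out[11] <- out[11] + k * psum[k + 1]
    if (psum[k + 1] > 0) out[12] <- out[12] - psum[k + 1] * log(psum[k + 1])
  }
  mu_d <- sum((0:(g - 1)) * pdiff)
  for (k in 0:(g - 1)) {
    if (pdiff[k + 1] > 0) out[13] <- out[13] - pdiff[k + 1] * log(pdiff[k + 1])
    out[14] <- out[14] + (k - mu_d)^2 * pdiff[k + 1]
  }
  names(out) <- haralick_feature_names()
  out
}
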