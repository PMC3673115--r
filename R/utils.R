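# Internal helpers shared across modules: seeded evaluation, reflective
# padding, and 8-connected component labelling.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive a sub-seed; stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) %% 2147483647 * 31 + as.numeric(offset) * 7919) %% 2147483647
}

# Symmetric (half-sample reflect) index vector for padding a length-n axis.
reflect_index <- function(n, pad) {
  if (pad == 0) return(seq_len(n))
  if (pad > n) {
    # fold repeatedly for very small images
    idx <- seq_len(n)
    while (length(idx) < n + 2 * pad) idx <- c(rev(idx), idx, rev(idx))
    mid <- (length(idx) - (n + 2 * pad)) %/% 2
    return(idx[(mid + 1):(mid + n + 2 * pad)])
  }
  c(pad:1, seq_len(n), n:(n - pad + 1))
}

# Pad a matrix by reflection on all sides.
reflect_pad <- function(x, pad_r, pad_c = pad_r) {
  x[reflect_index(nrow(x), pad_r), reflect_index(ncol(x), pad_c), drop = FALSE]
}

# 8-connected labelling. EBImage::bwlabel is 4-connected; diagonal-touching
# labels are merged afterwards with a union-find pass.
label_components <- function(mask) {
  mask <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lbl <- EBImage::bwlabel(mask)
  lbl <- matrix(as.integer(lbl), nrow(lbl), ncol(lbl))
  n <- max(lbl)
  if (n <= 1L) return(lbl)
  nr <- nrow(lbl); nc <- ncol(lbl)
  # diagonal neighbour pairs (down-right and down-left)
  a1 <- lbl[-nr, -nc]; b1 <- lbl[-1, -1]
  a2 <- lbl[-nr, -1];  b2 <- lbl[-1, -nc]
  pa <- c(a1[a1 > 0L & b1 > 0L & a1 != b1], a2[a2 > 0L & b2 > 0L & a2 != b2])
  pb <- c(b1[a1 > 0L & b1 > 0L & a1 != b1], b2[a2 > 0L & b2 > 0L & a2 != b2])
  if (length(pa)) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_along(pa)) {
      ra <- find(pa[k]); rb <- find(pb[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), find, integer(1))
    relab <- match(root, sort(unique(root)))
    nz <- lbl > 0L
    lbl[nz] <- relab[lbl[nz]]
  }
  lbl
}

# Count 8-connected components of a logical mask.
count_components <- function(mask) {
  max(label_components(mask))
}

as_pixel_matrix <- function(x) {
  if (inherits(x, "mammogram")) x$pixels else x
}
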