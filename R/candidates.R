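# Microcalcification candidate detection: threshold shift, dual-edge blob
# extraction, count-controlled iterative threshold search, and mask
# combination.

#' Threshold-shift an image
#'
#' `I'(x, y) = 0` where `I < T`, else `I - T`: the whole gray scale is shifted
#' down by `T` and clipped at zero rather than binarized.
#'
#' @param image Numeric matrix.
#' @param threshold Non-negative threshold `T`.
#' @return Numeric matrix.
#' @export
#' @examples
#' threshold_shift(matrix(c(5, 10), 1), 7)   # 0, 3
threshold_shift <- function(image, threshold) {
  stopifnot(threshold >= 0)
  x <- as_pixel_matrix(image)
  out <- x - threshold
  out[x < threshold] <- 0
  out
}

#' Candidate blobs from dual edge detection
#'
#' Sobel and Canny edge maps are computed independently; each map's closed
#' contours are filled, each filled image is opened with a 3x3 cross to break
#' single-pixel bridges between touching blobs, and the two binary results are
#' combined with a logical OR. Using two edge detectors reduces missed blobs:
#' a blob found by only one operator still appears in the union.
#'
#' @param image Numeric matrix (typically a threshold-shifted filtered image).
#' @return Logical matrix marking candidate pixels.
#' @export
edge_candidates <- function(image) {
  x <- as_pixel_matrix(image)
  cross <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  fill_open <- function(edges) {
    if (!any(edges)) return(edges)
    filled <- EBImage::fillHull(matrix(as.numeric(edges), nrow(edges))) > 0
    opened <- EBImage::opening(matrix(as.numeric(filled), nrow(filled)), cross)
    opened > 0
  }
  fill_open(sobel_edges(x)) | fill_open(canny_edges(x))
}

# Tight per-component statistics from an 8-connected label matrix.
components_table <- function(lbl, keep_pixels = TRUE) {
  n <- max(lbl)
  if (n == 0L) {
    return(tibble(
      id = integer(), area = integer(),
      row0 = integer(), row1 = integer(), col0 = integer(), col1 = integer(),
      delta_x = integer(), delta_y = integer(),
      centroid_row = numeric(), centroid_col = numeric(),
      pixels = list()
    ))
  }
  nz <- which(lbl > 0L)
  lab <- lbl[nz]
  rr <- (nz - 1L) %% nrow(lbl) + 1L
  cc <- (nz - 1L) %/% nrow(lbl) + 1L
  o <- order(lab)
  nz <- nz[o]; lab <- lab[o]; rr <- rr[o]; cc <- cc[o]
  area <- tabulate(lab, n)
  stops <- cumsum(area)
  starts <- c(1L, head(stops, -1) + 1L)
  r0 <- vapply(seq_len(n), function(i) min(rr[starts[i]:stops[i]]), integer(1))
  r1 <- vapply(seq_len(n), function(i) max(rr[starts[i]:stops[i]]), integer(1))
  c0 <- vapply(seq_len(n), function(i) min(cc[starts[i]:stops[i]]), integer(1))
  c1 <- vapply(seq_len(n), function(i) max(cc[starts[i]:stops[i]]), integer(1))
  crow <- vapply(seq_len(n), function(i) mean(rr[starts[i]:stops[i]]), numeric(1))
  ccol <- vapply(seq_len(n), function(i) mean(cc[starts[i]:stops[i]]), numeric(1))
  tibble(
    id = seq_len(n), area = area,
    row0 = r0, row1 = r1, col0 = c0, col1 = c1,
    delta_x = c1 - c0 + 1L, delta_y = r1 - r0 + 1L,
    centroid_row = crow, centroid_col = ccol,
    pixels = if (keep_pixels) {
      lapply(seq_len(n), function(i) nz[starts[i]:stops[i]])
    } else {
      rep(list(NULL), n)
    }
  )
}

#' Label a candidate mask
#'
#' Restricts the mask to the breast region (when given), labels 8-connected
#' components and tabulates per-candidate geometry: pixel set (linear
#' indices), area, tight bounding box, centroid, and the bounding-box width
#' `delta_x` and height `delta_y`.
#'
#' @param mask Logical matrix.
#' @param breast_mask Optional logical matrix; candidate pixels outside it are
#'   dropped.
#' @return A `candidate_mask`: list with elements `mask` (logical matrix) and
#'   `candidates` (tibble).
#' @export
label_candidates <- function(mask, breast_mask = NULL) {
  if (!is.null(breast_mask)) mask <- mask & breast_mask
  lbl <- label_components(mask)
  structure(
    list(mask = lbl > 0L, candidates = components_table(lbl)),
    class = "candidate_mask"
  )
}

#' @export
print.candidate_mask <- function(x, ...) {
  cat(sprintf("<candidate_mask> %d candidates on %d x %d raster",
              nrow(x$candidates), nrow(x$mask), ncol(x$mask)))
  if (!is.null(attr(x, "in_range")) && !attr(x, "in_range")) {
    cat(" (count target not attained)")
  }
  cat("\n")
  invisible(x)
}

#' Count-controlled iterative candidate search
#'
#' Starting from the Otsu threshold of the filtered image, the image is
#' threshold-shifted, candidate blobs are extracted via [edge_candidates()],
#' and the number of 8-connected components is compared with `count_range`.
#' The threshold is raised (multiplicatively, factor 1.05) while the count is
#' too high and lowered while too low; once two thresholds bracket the range
#' the search switches to bisection. It stops when the count falls inside the
#' range, when thresholds are exhausted, or after `max_iter` evaluations;
#' when the range is unattainable the closest-count mask is returned with
#' attribute `in_range = FALSE` and a warning.
#'
#' @param image Filtered image (numeric matrix), e.g. top-hat or wavelet
#'   output.
#' @param count_range Length-2 vector `(low, high)`, `low < high`.
#' @param breast_mask Optional logical matrix restricting candidates.
#' @param max_iter Evaluation cap (default 200).
#' @return A `candidate_mask` with attributes `threshold`, `count`,
#'   `in_range`.
#' @export
iterative_candidate_search <- function(image, count_range, breast_mask = NULL,
                                       max_iter = 200L) {
  stopifnot(length(count_range) == 2, count_range[1] < count_range[2])
  x <- as_pixel_matrix(image)
  lo <- count_range[1]; hi <- count_range[2]
  t_max <- max(x)
  t_min <- 0
  eval_count <- function(t) {
    m <- edge_candidates(threshold_shift(x, max(t, 0)))
    if (!is.null(breast_mask)) m <- m & breast_mask
    list(mask = m, count = count_components(m))
  }
  t <- tryCatch(otsu_threshold_real(x), error = function(e) t_max / 2)
  t <- max(t, t_min + 1e-9)
  best <- NULL; best_gap <- Inf
  t_over <- NA_real_   # highest threshold seen with count > hi (need larger t)
  t_under <- NA_real_  # lowest threshold seen with count < lo (need smaller t)
  for (i in seq_len(max_iter)) {
    r <- eval_count(t)
    gap <- if (r$count < lo) lo - r$count else if (r$count > hi) r$count - hi else 0
    if (gap < best_gap) {
      best_gap <- gap
      best <- list(t = t, r = r)
    }
    if (gap == 0) break
    if (r$count > hi) {
      t_over <- if (is.na(t_over)) t else max(t_over, t)
    } else {
      t_under <- if (is.na(t_under)) t else min(t_under, t)
    }
    # step size adapts to how far the count is from the range
    far <- (r$count > 2 * hi) || (r$count < lo / 2)
    up <- if (far) 1.4 else 1.05
    down <- if (far) 0.7 else 0.95
    if (!is.na(t_over) && !is.na(t_under) && t_over < t_under) {
      t_new <- (t_over + t_under) / 2           # bracketed: bisect
      if (abs(t_new - t) < 1e-6 * max(1, t_max)) break
      t <- t_new
    } else if (r$count > hi) {
      t <- t * up + 1e-6
      if (t >= t_max) break
    } else {
      t <- t * down
      if (t <= 0.005 * max(1, t_max)) {
        # nearly at zero threshold without reaching `lo`: check the floor
        r0 <- eval_count(t_min)
        gap0 <- if (r0$count < lo) lo - r0$count else if (r0$count > hi) r0$count - hi else 0
        if (gap0 <= best_gap) {
          best_gap <- gap0
          best <- list(t = t_min, r = r0)
        }
        if (gap0 > 0 && r0$count < lo) break    # range unattainable from below
        if (gap0 == 0) break
        t_over <- t_min
      }
    }
  }
  in_range <- best_gap == 0
  if (!in_range) {
    warn(sprintf(
      "candidate count target [%d, %d] not attained; closest count %d at threshold %.4g",
      lo, hi, best$r$count, best$t))
  }
  cm <- label_candidates(best$r$mask)
  attr(cm, "threshold") <- best$t
  attr(cm, "count") <- best$r$count
  attr(cm, "in_range") <- in_range
  cm
}

#' Combine two candidate masks with a logical OR
#'
#' @param m1,m2 `candidate_mask` objects or logical matrices of equal shape.
#' @param breast_mask Optional logical matrix restricting candidates.
#' @return A re-labelled `candidate_mask`.
#' @export
combine_masks <- function(m1, m2, breast_mask = NULL) {
  a <- if (inherits(m1, "candidate_mask")) m1$mask else m1
  b <- if (inherits(m2, "candidate_mask")) m2$mask else m2
  if (!identical(dim(a), dim(b))) abort("mask shape mismatch")
  label_candidates(a | b, breast_mask)
}
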