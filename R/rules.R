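# Knowledge-based noise rules: size, line-like shape, and isolation. Each
# rule only removes rows from the candidate tibble (never adds or edits), and
# they run in the order size -> shape -> isolation.

#' Bounding-box elongation
#'
#' `max(dx/dy, dy/dx)` of the candidate bounding box; always >= 1 and
#' symmetric under transposition.
#'
#' @param delta_x,delta_y Bounding-box width and height in pixels (>= 1).
#' @return Numeric vector of elongations.
#' @export
#' @examples
#' elongation(7, 2)   # 3.5
elongation <- function(delta_x, delta_y) {
  if (any(delta_x < 1) || any(delta_y < 1)) abort("degenerate bounding box")
  pmax(delta_x / delta_y, delta_y / delta_x)
}

#' Bounding-box compactness
#'
#' `area / (dx * dy)`: the fraction of the bounding box covered by candidate
#' pixels, in `(0, 1]`.
#'
#' @param area Pixel count of the candidate.
#' @param delta_x,delta_y Bounding-box width and height in pixels (>= 1).
#' @return Numeric vector of compactness values.
#' @export
compactness <- function(area, delta_x, delta_y) {
  if (any(delta_x < 1) || any(delta_y < 1)) abort("degenerate bounding box")
  area / (delta_x * delta_y)
}

#' Size rule: drop large candidates
#'
#' Removes every candidate strictly larger than `max_area` pixels (default
#' 100): large blobs are skin markers or macro-calcifications, not the small
#' spots this detector targets.
#'
#' @param candidates Candidate tibble (needs an `area` column).
#' @param max_area Strict upper area bound (kept when `area <= max_area`).
#' @return Filtered tibble.
#' @export
apply_size_rule <- function(candidates, max_area = 100) {
  filter(candidates, .data$area <= max_area)
}

#' Shape rule: drop line-like candidates
#'
#' A candidate is line-like when it is stretched (elongation > 3.5) or sparse
#' in its bounding box (compactness < 0.38). In the default `"or"` mode a
#' candidate failing either test is removed, which catches both axis-aligned
#' lines (compactness 1 but elongated) and diagonal lines (elongation 1 but
#' sparse); `"and"` removes only candidates failing both.
#'
#' @param candidates Candidate tibble (needs `area`, `delta_x`, `delta_y`).
#' @param mode `"or"` (default) or `"and"`.
#' @param max_elongation,min_compactness Strict decision boundaries
#'   (defaults 3.5 and 0.38).
#' @return Filtered tibble.
#' @export
apply_shape_rule <- function(candidates, mode = c("or", "and"),
                             max_elongation = 3.5, min_compactness = 0.38) {
  mode <- match.arg(mode)
  if (nrow(candidates) == 0) return(candidates)
  e <- elongation(candidates$delta_x, candidates$delta_y)
  k <- compactness(candidates$area, candidates$delta_x, candidates$delta_y)
  noisy <- if (mode == "or") {
    e > max_elongation | k < min_compactness
  } else {
    e > max_elongation & k < min_compactness
  }
  candidates[!noisy, , drop = FALSE]
}

#' Isolation rule: drop candidates without local company
#'
#' Clusters need at least three member microcalcifications, so a candidate
#' with fewer than `min_neighbors` candidates (itself included) inside the
#' 1 cm x 1 cm axis-aligned square centred on its centroid is an isolated spot
#' and is removed. The window half-width in pixels is
#' `5 mm / pixel_spacing_mm`.
#'
#' @param candidates Candidate tibble (needs `centroid_row`, `centroid_col`).
#' @param pixel_spacing_mm Pixel size in millimetres.
#' @param window_mm Side of the counting square in millimetres (default 10).
#' @param min_neighbors Minimum in-window count to survive (default 3).
#' @return Filtered tibble.
#' @export
apply_isolation_rule <- function(candidates, pixel_spacing_mm,
                                 window_mm = 10, min_neighbors = 3) {
  stopifnot(pixel_spacing_mm > 0)
  n <- nrow(candidates)
  if (n == 0) return(candidates)
  half <- window_mm / 2 / pixel_spacing_mm
  dr <- abs(outer(candidates$centroid_row, candidates$centroid_row, "-")) <= half
  dc <- abs(outer(candidates$centroid_col, candidates$centroid_col, "-")) <= half
  counts <- rowSums(dr & dc)
  candidates[counts >= min_neighbors, , drop = FALSE]
}

#' Apply all three knowledge rules
#'
#' Size, then shape, then isolation — the isolation rule runs last so that
#' removed noise cannot prop up an otherwise isolated spot.
#'
#' @param candidates Candidate tibble.
#' @param config An [mcc_config()] (supplies the shape-rule mode and pixel
#'   spacing).
#' @return Filtered tibble.
#' @export
apply_knowledge_rules <- function(candidates, config = mcc_config()) {
  candidates |>
    apply_size_rule() |>
    apply_shape_rule(mode = config$shape_rule_mode) |>
    apply_isolation_rule(pixel_spacing_mm = config$pixel_spacing_mm)
}
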