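#' Mammogram image container
#'
#' A light wrapper around a 2-D non-negative integer raster together with its
#' declared bit depth (14 for raw detector data, 12 after the inverted
#' logarithmic transform) and the isotropic pixel spacing in millimetres.
#'
#' @param pixels Numeric matrix of non-negative integers.
#' @param bit_depth One of 12, 14 or 16; all pixels must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param pixel_spacing_mm Positive pixel size in millimetres.
#'
#' @return An object of class `mammogram`.
#' @export
#' @examples
#' m <- mammogram(matrix(0:3, 2, 2), bit_depth = 14)
#' dim(m$pixels)
mammogram <- function(pixels, bit_depth, pixel_spacing_mm = 0.1) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!bit_depth %in% c(12L, 14L, 16L)) {
    abort(sprintf("unsupported bit depth %s (expected 12, 14 or 16)", bit_depth))
  }
  if (any(pixels < 0) || any(pixels > 2^bit_depth - 1)) {
    abort(sprintf("pixel values outside [0, %d]", 2^bit_depth - 1))
  }
  if (any(pixels != round(pixels))) {
    abort("pixel values must be integers")
  }
  stopifnot(pixel_spacing_mm > 0)
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         pixel_spacing_mm = pixel_spacing_mm),
    class = "mammogram"
  )
}

#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf("<mammogram> %d x %d, %d-bit, %.3g mm/px, range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$pixel_spacing_mm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.mammogram <- function(x) dim(x$pixels)

infer_bit_depth <- function(pixels) {
  mx <- max(pixels)
  if (mx <= 4095) 12L else if (mx <= 16383) 14L else 16L
}

#' Read a mammogram from a 16-bit grayscale TIFF or PNG
#'
#' Single-channel 16-bit containers are read as integer rasters. The declared
#' bit depth may be given explicitly; otherwise it is inferred from the value
#' range (values <= 4095 declare 12-bit, <= 16383 declare 14-bit, else
#' 16-bit). Pixel spacing is not carried by these containers and comes from
#' the caller (typically `mcc_config()$pixel_spacing_mm`).
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param bit_depth Optional explicit bit depth (12, 14 or 16).
#' @param pixel_spacing_mm Pixel size in millimetres.
#'
#' @return A [mammogram()].
#' @export
read_image <- function(path, bit_depth = NULL, pixel_spacing_mm = 0.1) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    px <- png::readPNG(path)
    # readPNG returns [0,1]; rescale to the stored 16-bit integers
    px <- round(px * 65535)
  } else {
    abort(sprintf("unsupported image format '.%s' (expected TIFF or PNG)", ext))
  }
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] > 1L) abort("multi-channel image: expected single-channel grayscale")
    px <- px[, , 1]
  }
  bd <- if (is.null(bit_depth)) infer_bit_depth(px) else as.integer(bit_depth)
  mammogram(px, bit_depth = bd, pixel_spacing_mm = pixel_spacing_mm)
}

#' Write a mammogram to a 16-bit grayscale TIFF
#'
#' Values are stored as 16-bit samples regardless of the declared bit depth, so
#' write/read round-trips are lossless for 12- and 14-bit data.
#'
#' @param image A [mammogram()].
#' @param path Output path ending in `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "mammogram"))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff")) {
    abort("write_image stores 16-bit TIFF; use a .tif/.tiff path")
  }
  tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Ground-truth annotations for one mammogram
#'
#' Holds the manually marked microcalcification centre points and the
#' rectangles enclosing microcalcification clusters. Coordinates are 1-based
#' `(row, col)` pixel positions; rectangles are inclusive
#' `[row0, row1] x [col0, col1]` with `row0 <= row1`, `col0 <= col1`.
#'
#' @param mc_points Tibble/data frame with columns `row`, `col` (may be empty).
#' @param mcc_rects Tibble/data frame with columns `row0`, `col0`, `row1`,
#'   `col1` (may be empty).
#'
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(mc_points = NULL, mcc_rects = NULL) {
  pts <- if (is.null(mc_points) || nrow(as.data.frame(mc_points)) == 0) {
    tibble(row = numeric(), col = numeric())
  } else {
    as_tibble(mc_points)[, c("row", "col")]
  }
  rcs <- if (is.null(mcc_rects) || nrow(as.data.frame(mcc_rects)) == 0) {
    tibble(row0 = numeric(), col0 = numeric(), row1 = numeric(), col1 = numeric())
  } else {
    as_tibble(mcc_rects)[, c("row0", "col0", "row1", "col1")]
  }
  if (nrow(rcs) && any(rcs$row1 < rcs$row0 | rcs$col1 < rcs$col0)) {
    abort("every ground-truth rectangle needs row0 <= row1 and col0 <= col1")
  }
  structure(list(mc_points = pts, mcc_rects = rcs), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d MC points, %d MCC rectangles\n",
              nrow(x$mc_points), nrow(x$mcc_rects)))
  invisible(x)
}

#' Validate ground truth against image bounds
#'
#' @param gt A [ground_truth()].
#' @param image A [mammogram()] or a `dim()`-like integer vector.
#' @return `gt`, invisibly, or an error when a coordinate falls outside the
#'   raster or a rectangle has non-positive extent.
#' @export
validate_ground_truth <- function(gt, image) {
  d <- if (inherits(image, "mammogram")) dim(image$pixels) else as.integer(image)
  p <- gt$mc_points
  if (nrow(p) && (any(p$row < 1) || any(p$col < 1) ||
                  any(p$row > d[1]) || any(p$col > d[2]))) {
    abort("MC point outside image bounds")
  }
  r <- gt$mcc_rects
  if (nrow(r) && (any(r$row0 < 1) || any(r$col0 < 1) ||
                  any(r$row1 > d[1]) || any(r$col1 > d[2]))) {
    abort("MCC rectangle outside image bounds")
  }
  invisible(gt)
}

#' Read or write ground-truth annotations as JSON
#'
#' The JSON object carries two keys: `mc_points` (array of `[row, col]`
#' pairs) and `mcc_rects` (array of `[row0, col0, row1, col1]` quadruples),
#' both 1-based inclusive. Round-trips are lossless.
#'
#' @param path JSON file path.
#' @param image Optional [mammogram()] (or dim vector) to validate
#'   coordinates against.
#' @return A [ground_truth()].
#' @export
read_annotations <- function(path, image = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!all(c("mc_points", "mcc_rects") %in% names(obj))) {
    abort("malformed annotation file: keys 'mc_points' and 'mcc_rects' required")
  }
  pts <- obj$mc_points
  pts <- if (length(pts) == 0) NULL else {
    pts <- matrix(as.numeric(pts), ncol = 2,
                  dimnames = list(NULL, c("row", "col")))
    as_tibble(pts)
  }
  rcs <- obj$mcc_rects
  rcs <- if (length(rcs) == 0) NULL else {
    rcs <- matrix(as.numeric(rcs), ncol = 4,
                  dimnames = list(NULL, c("row0", "col0", "row1", "col1")))
    as_tibble(rcs)
  }
  gt <- ground_truth(pts, rcs)
  if (nrow(gt$mc_points) && any(gt$mc_points$row < 1 | gt$mc_points$col < 1)) {
    abort("MC point with non-positive coordinate")
  }
  if (!is.null(image)) validate_ground_truth(gt, image)
  gt
}

#' @rdname read_annotations
#' @param gt A [ground_truth()].
#' @export
write_annotations <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  obj <- list(
    mc_points = if (nrow(gt$mc_points)) unname(as.matrix(gt$mc_points)) else list(),
    mcc_rects = if (nrow(gt$mcc_rects)) unname(as.matrix(gt$mcc_rects)) else list()
  )
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}
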