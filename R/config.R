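#' Run configuration for the detection pipeline
#'
#' Collects every tunable the pipeline reads: the RNG seed, the spatial
#' calibration, the top-hat structuring-element radius, the target candidate
#' counts for the two detection branches, GLCM quantization, the analysis
#' window, the normal-to-MC training ratio, the ensemble voting threshold and
#' the shape-rule combination mode.
#'
#' Physical-distance rules (the 1 cm^2 isolation window, the 1 cm cluster
#' linkage) convert millimetres to pixels through `pixel_spacing_mm`; the
#' mammograms this pipeline targets do not carry a standard resolution tag, so
#' the calibration is an explicit configuration value (default 0.1 mm/pixel,
#' i.e. 1 cm = 100 pixels).
#'
#' @param seed Integer seed used to derive every stochastic sub-step.
#' @param pixel_spacing_mm Isotropic pixel size in millimetres (> 0).
#' @param tophat_radius_px Disk radius of the top-hat structuring element.
#' @param candidate_range_tophat Length-2 integer vector `(low, high)`: the
#'   admissible candidate count for the top-hat branch of the iterative search.
#' @param candidate_range_wavelet Same for the wavelet branch.
#' @param glcm_levels Number of gray levels for GLCM quantization.
#' @param window_size Side of the square texture window (even, >= 8).
#' @param normal_to_mc_ratio How many MC-absent training patterns are sampled
#'   per MC-present pattern.
#' @param voting_threshold_N Integer in 1..18, or `"auto"` to pick the
#'   threshold from the training fROC (largest sensitivity with < 1 FP/image).
#' @param shape_rule_mode `"or"` (default) or `"and"`: how the elongation and
#'   compactness tests combine in the line-like noise rule.
#'
#' @return A list of class `mcc_config`.
#' @export
#' @examples
#' cfg <- mcc_config(seed = 1)
#' cfg$candidate_range_tophat
mcc_config <- function(seed = 1L,
                       pixel_spacing_mm = 0.1,
                       tophat_radius_px = 7L,
                       candidate_range_tophat = c(450L, 550L),
                       candidate_range_wavelet = c(350L, 400L),
                       glcm_levels = 64L,
                       window_size = 16L,
                       normal_to_mc_ratio = 5,
                       voting_threshold_N = "auto",
                       shape_rule_mode = c("or", "and")) {
  shape_rule_mode <- match.arg(shape_rule_mode)
  stopifnot(
    is.numeric(seed), length(seed) == 1,
    pixel_spacing_mm > 0,
    tophat_radius_px >= 1,
    length(candidate_range_tophat) == 2,
    candidate_range_tophat[1] < candidate_range_tophat[2],
    length(candidate_range_wavelet) == 2,
    candidate_range_wavelet[1] < candidate_range_wavelet[2],
    glcm_levels >= 2,
    window_size >= 8, window_size %% 2 == 0,
    normal_to_mc_ratio > 0
  )
  if (!identical(voting_threshold_N, "auto")) {
    stopifnot(is.numeric(voting_threshold_N),
              voting_threshold_N >= 1, voting_threshold_N <= 18)
  }
  structure(
    list(
      seed = as.integer(seed),
      pixel_spacing_mm = pixel_spacing_mm,
      tophat_radius_px = as.integer(tophat_radius_px),
      candidate_range_tophat = as.integer(candidate_range_tophat),
      candidate_range_wavelet = as.integer(candidate_range_wavelet),
      glcm_levels = as.integer(glcm_levels),
      window_size = as.integer(window_size),
      normal_to_mc_ratio = normal_to_mc_ratio,
      voting_threshold_N = voting_threshold_N,
      shape_rule_mode = shape_rule_mode
    ),
    class = "mcc_config"
  )
}

#' @export
print.mcc_config <- function(x, ...) {
  cat("<mcc_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
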