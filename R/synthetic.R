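# Seeded synthetic mammogram generator. A phantom is designed in the
# display (ILT) domain -- a half-elliptical breast on a dark background,
# smooth low-frequency texture, bright Gaussian microcalcification spots in
# compact clusters, isolated spots, thin line artifacts, large marker blobs
# and additive noise -- and then encoded back through the inverse ILT curve
# to the 14-bit raw convention, so the full pipeline runs from the start.

#' Specification of a synthetic mammogram
#'
#' Defaults describe the benchmark condition: a 384 x 384 raster at
#' 0.2 mm/pixel (a 7.7 cm field, the working resolution after the
#' downsampling customary in mammography CAD), smooth uneven background,
#' two clusters of eight microcalcifications each within a 4 mm radius (so
#' every cluster satisfies the 1 cm nearest-neighbour criterion by
#' construction), three isolated microcalcifications, two thin line
#' artifacts, one large marker blob, and Gaussian noise of 25 gray levels
#' (12-bit scale) inside the breast.
#'
#' @param image_shape Length-2 integer vector (rows, cols).
#' @param pixel_spacing_mm Pixel size in millimetres.
#' @param background_level Mean display-domain tissue level.
#' @param background_amplitude Amplitude of the smooth background blobs.
#' @param background_scale_px Correlation length of the background blobs.
#' @param n_background_blobs Number of smooth background blobs.
#' @param ramp_amplitude Left-to-right linear ramp amplitude.
#' @param noise_sigma Gaussian noise SD inside the breast (display units).
#' @param n_speckle_spots Number of faint spot-like speckle bumps inside the
#'   breast (film-grain/quantum-mottle clumps; these drive the abundant
#'   low-contrast peaks the count-controlled candidate search operates on).
#' @param speckle_amplitude_range Display-domain speckle amplitude range
#'   (well below `mc_amplitude_range`).
#' @param speckle_sigma_range_px Speckle bump scale range in pixels.
#' @param n_clusters Number of MC clusters.
#' @param mcs_per_cluster MCs per cluster (>= 3).
#' @param cluster_radius_mm Cluster placement radius (<= 5 so the 1 cm
#'   criterion holds).
#' @param mc_amplitude_range Display-domain spot amplitude range.
#' @param mc_sigma_range_px MC spot scale range in pixels.
#' @param mc_sharpness Super-Gaussian exponent of the MC profile (1 =
#'   Gaussian; the default 2 gives the flat top and steep edge of a calcium
#'   deposit, which is what distinguishes an MC texturally from smooth
#'   mottle of similar size).
#' @param n_isolated_mcs Isolated (non-clustered) MCs.
#' @param n_line_artifacts Thin line artifacts.
#' @param n_marker_blobs Marker blobs (area > 100 px).
#' @param seed Generator seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_shape = c(384L, 384L),
                           pixel_spacing_mm = 0.2,
                           background_level = 800,
                           background_amplitude = 300,
                           background_scale_px = 60,
                           n_background_blobs = 6L,
                           ramp_amplitude = 150,
                           noise_sigma = 12,
                           n_speckle_spots = 2200L,
                           speckle_amplitude_range = c(80, 280),
                           speckle_sigma_range_px = c(0.9, 1.6),
                           n_clusters = 2L,
                           mcs_per_cluster = 8L,
                           cluster_radius_mm = 4,
                           mc_amplitude_range = c(350, 650),
                           mc_sigma_range_px = c(1.6, 2.4),
                           mc_sharpness = 2,
                           n_isolated_mcs = 3L,
                           n_line_artifacts = 2L,
                           n_marker_blobs = 1L,
                           seed = 20130411) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 64),
            pixel_spacing_mm > 0,
            n_clusters >= 0, mcs_per_cluster >= 3,
            cluster_radius_mm > 0, cluster_radius_mm <= 5,
            length(mc_amplitude_range) == 2, length(mc_sigma_range_px) == 2,
            n_isolated_mcs >= 0, n_line_artifacts >= 0, n_marker_blobs >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Half-elliptical breast support against the left image edge.
breast_support <- function(shape) {
  h <- shape[1]; w <- shape[2]
  r0 <- (h + 1) / 2
  ry <- 0.46 * h; rx <- 0.75 * w
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  val <- ((rr - r0) / ry)^2 + ((cc - 1) / rx)^2
  list(mask = val <= 1, val = val)
}

# Rejection-sample `n` points with ellipse value <= frac^2 and pairwise
# distance >= min_sep, at least `clear` px from given points.
sample_breast_points <- function(sup, n, frac, min_sep = 0,
                                 avoid = NULL, avoid_dist = 0) {
  if (n == 0) return(matrix(numeric(), 0, 2))
  h <- nrow(sup$mask); w <- ncol(sup$mask)
  pts <- matrix(numeric(), 0, 2)
  tries <- 0
  while (nrow(pts) < n && tries < 20000) {
    tries <- tries + 1
    p <- c(runif(1, 2, h - 1), runif(1, 2, w - 1))
    v <- ((p[1] - (h + 1) / 2) / (0.46 * h))^2 + ((p[2] - 1) / (0.75 * w))^2
    if (v > frac^2) next
    ok <- TRUE
    if (nrow(pts) && min_sep > 0) {
      ok <- all(sqrt(rowSums(sweep(pts, 2, p)^2)) >= min_sep)
    }
    if (ok && !is.null(avoid) && nrow(avoid) && avoid_dist > 0) {
      ok <- all(sqrt(rowSums(sweep(avoid, 2, p)^2)) >= avoid_dist)
    }
    if (ok) pts <- rbind(pts, p)
  }
  if (nrow(pts) < n) abort("could not place objects inside the breast support")
  pts
}

add_gaussian_spot <- function(scene, center, amplitude, sigma, sharpness = 1) {
  h <- nrow(scene); w <- ncol(scene)
  r <- max(2L, ceiling(4 * sigma))
  rs <- max(1, round(center[1]) - r):min(h, round(center[1]) + r)
  cs <- max(1, round(center[2]) - r):min(w, round(center[2]) + r)
  d2 <- outer((rs - center[1])^2, (cs - center[2])^2, "+")
  # sharpness 1 = Gaussian; > 1 = super-Gaussian (flat top, steep edge)
  g <- exp(-(d2 / (2 * sigma^2))^sharpness)
  scene[rs, cs] <- scene[rs, cs] + amplitude * g
  scene
}

#' Generate one synthetic mammogram with ground truth
#'
#' See [synthetic_spec()] for what the phantom contains. The returned image
#' is 14-bit raw (pre-ILT); applying [ilt_transform()] recovers the designed
#' display-domain appearance up to quantization.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_mammogram`: `image` (14-bit
#'   [mammogram()]), `truth` ([ground_truth()]; cluster and isolated MC
#'   points, one rectangle per cluster), `breast_mask` (the generator's true
#'   support), and `spec`.
#' @export
generate_mammogram <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    h <- spec$image_shape[1]; w <- spec$image_shape[2]
    sup <- breast_support(c(h, w))
    scene <- matrix(15, h, w)
    # smooth uneven background inside the breast
    bg <- matrix(spec$background_level, h, w)
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    bg <- bg + spec$ramp_amplitude * (cc - 1) / (w - 1)
    blobs <- sample_breast_points(sup, spec$n_background_blobs, frac = 0.95)
    for (i in seq_len(nrow(blobs))) {
      amp <- runif(1, -1, 1) * spec$background_amplitude
      sg <- runif(1, 0.7, 1.5) * spec$background_scale_px
      bg <- bg + amp * exp(-((rr - blobs[i, 1])^2 + (cc - blobs[i, 2])^2) /
                             (2 * sg^2))
    }
    scene[sup$mask] <- pmax(bg[sup$mask], 100)

    clr_px <- spec$cluster_radius_mm / spec$pixel_spacing_mm
    sep_px <- 25 / spec$pixel_spacing_mm          # 2.5 cm between clusters
    centers <- sample_breast_points(sup, spec$n_clusters, frac = 0.7,
                                    min_sep = sep_px)
    mc_points <- matrix(numeric(), 0, 2)
    rects <- NULL
    for (k in seq_len(spec$n_clusters)) {
      pts <- matrix(numeric(), 0, 2)
      while (nrow(pts) < spec$mcs_per_cluster) {
        ang <- runif(1, 0, 2 * pi)
        rad <- sqrt(runif(1)) * clr_px
        p <- centers[k, ] + rad * c(cos(ang), sin(ang))
        p <- pmin(pmax(p, 2), c(h, w) - 1)
        if (nrow(pts) == 0 ||
            min(sqrt(rowSums(sweep(pts, 2, p)^2))) >= 8) {
          pts <- rbind(pts, p)
        }
      }
      for (i in seq_len(nrow(pts))) {
        scene <- add_gaussian_spot(
          scene, pts[i, ],
          runif(1, spec$mc_amplitude_range[1], spec$mc_amplitude_range[2]),
          runif(1, spec$mc_sigma_range_px[1], spec$mc_sigma_range_px[2]),
          spec$mc_sharpness)
      }
      mc_points <- rbind(mc_points, pts)
      pad <- 3   # rectangles drawn as small as possible around the spots
      rects <- rbind(rects, c(
        max(1, floor(min(pts[, 1])) - pad), max(1, floor(min(pts[, 2])) - pad),
        min(h, ceiling(max(pts[, 1])) + pad), min(w, ceiling(max(pts[, 2])) + pad)))
    }
    iso <- sample_breast_points(sup, spec$n_isolated_mcs, frac = 0.85,
                                min_sep = 30,
                                avoid = if (spec$n_clusters) centers else NULL,
                                avoid_dist = 15 / spec$pixel_spacing_mm)
    for (i in seq_len(nrow(iso))) {
      scene <- add_gaussian_spot(
        scene, iso[i, ],
        runif(1, spec$mc_amplitude_range[1], spec$mc_amplitude_range[2]),
        runif(1, spec$mc_sigma_range_px[1], spec$mc_sigma_range_px[2]),
        spec$mc_sharpness)
    }
    mc_points <- rbind(mc_points, iso)

    # thin line artifacts (breast border sections, fibres)
    lines <- sample_breast_points(sup, spec$n_line_artifacts, frac = 0.85,
                                  avoid = if (spec$n_clusters) centers else NULL,
                                  avoid_dist = 10 / spec$pixel_spacing_mm)
    for (i in seq_len(nrow(lines))) {
      ang <- runif(1, 0, pi)
      len <- runif(1, 40, 80)
      t <- seq(-len / 2, len / 2, by = 0.5)
      pr <- pmin(pmax(round(lines[i, 1] + t * sin(ang)), 1), h)
      pc <- pmin(pmax(round(lines[i, 2] + t * cos(ang)), 1), w)
      idx <- unique(cbind(pr, pc))
      scene[idx] <- scene[idx] + 250
    }

    # large marker blobs (area > 100 px)
    markers <- sample_breast_points(sup, spec$n_marker_blobs, frac = 0.8,
                                    avoid = if (spec$n_clusters) centers else NULL,
                                    avoid_dist = 15 / spec$pixel_spacing_mm)
    for (i in seq_len(nrow(markers))) {
      d2 <- (rr - markers[i, 1])^2 + (cc - markers[i, 2])^2
      scene[d2 <= 9^2] <- scene[d2 <= 9^2] + 500
    }

    # spot-like speckle: many faint multi-pixel bumps inside the breast
    if (spec$n_speckle_spots > 0) {
      inb <- which(sup$mask)
      pick <- sample(inb, spec$n_speckle_spots, replace = TRUE)
      prr <- (pick - 1) %% h + 1
      pcc <- (pick - 1) %/% h + 1
      amp <- runif(spec$n_speckle_spots, spec$speckle_amplitude_range[1],
                   spec$speckle_amplitude_range[2])
      sg <- runif(spec$n_speckle_spots, spec$speckle_sigma_range_px[1],
                  spec$speckle_sigma_range_px[2])
      for (i in seq_len(spec$n_speckle_spots)) {
        scene <- add_gaussian_spot(scene, c(prr[i], pcc[i]), amp[i], sg[i])
      }
    }

    # noise: full strength inside the breast, faint outside
    scene <- scene + rnorm(h * w, sd = 3) +
      sup$mask * rnorm(h * w, sd = max(spec$noise_sigma - 3, 0))
    scene <- pmin(pmax(scene, 0), 3500)

    raw <- matrix(pmin(pmax(round(ilt_inverse(scene)), 0), 16383), h, w)
    truth <- ground_truth(
      mc_points = if (nrow(mc_points)) {
        tibble(row = mc_points[, 1], col = mc_points[, 2])
      } else {
        NULL
      },
      mcc_rects = if (!is.null(rects)) {
        tibble(row0 = rects[, 1], col0 = rects[, 2],
               row1 = rects[, 3], col1 = rects[, 4])
      } else {
        NULL
      }
    )
    structure(
      list(image = mammogram(raw, bit_depth = 14L,
                             pixel_spacing_mm = spec$pixel_spacing_mm),
           truth = truth, breast_mask = sup$mask, spec = spec),
      class = "synthetic_mammogram"
    )
  })
}

#' @export
print.synthetic_mammogram <- function(x, ...) {
  cat(sprintf("<synthetic_mammogram> %d x %d, %d MC points, %d clusters\n",
              nrow(x$image$pixels), ncol(x$image$pixels),
              nrow(x$truth$mc_points), nrow(x$truth$mcc_rects)))
  invisible(x)
}

#' Generate a set of synthetic mammograms
#'
#' @param n_images Number of phantoms.
#' @param spec Base [synthetic_spec()]; each image gets a seed derived from
#'   `seed`.
#' @param seed Master seed (defaults to the spec's seed).
#' @return List of `synthetic_mammogram` objects.
#' @export
generate_dataset <- function(n_images, spec = synthetic_spec(), seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  lapply(seq_len(n_images), function(i) {
    s <- spec
    s$seed <- derive_seed(seed, i)
    generate_mammogram(s)
  })
}

#' Synthetic feature matrices for selection and training tests
#'
#' Builds 18 two-class feature matrices of 56 columns in which a known subset
#' of columns carries Gaussian class separation (`separation` SD units
#' between class means) and the remaining columns are independent noise. The
#' informative column indices are drawn once (seeded) and shared by all 18
#' matrices.
#'
#' @param n_per_class Patterns per class in each matrix.
#' @param n_informative Number of informative columns (<= 56).
#' @param separation Class-mean separation in SD units.
#' @param seed Generator seed.
#' @param n_features Total columns (default 56).
#' @return List with `matrices` (named list of 18 tibbles with a `label`
#'   column, class `feature_matrices`) and `informative` (integer indices).
#' @export
generate_feature_toy <- function(n_per_class = 60L, n_informative = 3L,
                                 separation = 2, seed = 1L,
                                 n_features = 56L) {
  stopifnot(n_informative <= n_features)
  with_seed(seed, {
    informative <- sort(sample.int(n_features, n_informative))
    labels <- rep(c(1, 0), each = n_per_class)
    mats <- lapply(feature_image_names(), function(nm) {
      x <- matrix(rnorm(2 * n_per_class * n_features), 2 * n_per_class)
      x[labels == 1, informative] <- x[labels == 1, informative] + separation
      colnames(x) <- feature_vector_names()[seq_len(n_features)]
      tb <- as_tibble(x)
      tb$candidate_id <- seq_len(nrow(tb))
      tb$label <- labels
      tb[, c("candidate_id", colnames(x), "label")]
    })
    names(mats) <- feature_image_names()
    list(matrices = structure(mats, class = "feature_matrices"),
         informative = informative)
  })
}
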