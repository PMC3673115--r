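# Cluster-level evaluation: single-linkage grouping of accepted candidates
# into MCC detections, Kallergi-style matching against ground-truth
# rectangles, sensitivity / FP-per-image scoring, the fROC over the voting
# threshold, and the ROC area.

#' Group accepted candidates into cluster detections
#'
#' Single-linkage clustering of candidate centroids with link distance
#' `link_mm` (default 10 mm = 1 cm); groups with at least `min_members`
#' candidates (default 3) become cluster detections whose rectangle is the
#' tight bounding box over the member pixel sets.
#'
#' @param candidates Candidate tibble (needs centroids and bounding boxes).
#' @param pixel_spacing_mm Pixel size in millimetres.
#' @param link_mm Nearest-neighbour link distance in millimetres.
#' @param min_members Minimum cluster size (default 3).
#' @return Tibble of detections: `cluster`, `n_members`, `row0`, `col0`,
#'   `row1`, `col1`, `member_ids` (list column).
#' @export
cluster_mcs <- function(candidates, pixel_spacing_mm, link_mm = 10,
                        min_members = 3L) {
  empty <- tibble(cluster = integer(), n_members = integer(),
                  row0 = integer(), col0 = integer(),
                  row1 = integer(), col1 = integer(), member_ids = list())
  n <- nrow(candidates)
  if (n == 0) return(empty)
  link_px <- link_mm / pixel_spacing_mm
  grp <- if (n == 1) {
    1L
  } else {
    h <- hclust(dist(cbind(candidates$centroid_row, candidates$centroid_col)),
                method = "single")
    cutree(h, h = link_px)
  }
  out <- candidates |>
    mutate(cluster = grp) |>
    group_by(.data$cluster) |>
    summarise(
      n_members = dplyr::n(),
      row0 = min(.data$row0), col0 = min(.data$col0),
      row1 = max(.data$row1), col1 = max(.data$col1),
      member_ids = list(.data$id),
      .groups = "drop"
    ) |>
    filter(.data$n_members >= min_members)
  if (nrow(out) == 0) empty else out
}

rect_area <- function(r) {
  (r$row1 - r$row0 + 1) * (r$col1 - r$col0 + 1)
}

rect_intersection_area <- function(a, b) {
  dr <- min(a$row1, b$row1) - max(a$row0, b$row0) + 1
  dc <- min(a$col1, b$col1) - max(a$col0, b$col0) + 1
  if (dr <= 0 || dc <= 0) 0 else dr * dc
}

#' Kallergi match test for one detection/truth rectangle pair
#'
#' A detection is a true positive for a ground-truth cluster when the
#' intersection covers more than half of the truth rectangle
#' (`intersection / truth area > 0.5`) and the detection rectangle is at most
#' four times the truth area. A detection failing either test counts as a
#' false positive, and a truth claimed by no detection counts as a false
#' negative.
#'
#' @param det_rect,gt_rect Lists/one-row tibbles with `row0`, `col0`, `row1`,
#'   `col1` (1-based inclusive).
#' @return List with logical `tp` and the `overlap_ratio`
#'   (intersection / truth area).
#' @export
kallergi_match <- function(det_rect, gt_rect) {
  inter <- rect_intersection_area(det_rect, gt_rect)
  ratio <- inter / rect_area(gt_rect)
  tp <- ratio > 0.5 && rect_area(det_rect) <= 4 * rect_area(gt_rect)
  list(tp = tp, overlap_ratio = ratio)
}

#' Score cluster detections against ground truth
#'
#' Per image, detection/truth pairs passing the Kallergi tests are matched
#' greedily one-to-one by descending overlap ratio. Sensitivity is
#' `TP / (TP + FN)` over all truths; the FP rate is the total number of
#' unmatched detections divided by the number of images.
#'
#' @param detections Tibble of detection rectangles with an `image_id`
#'   column.
#' @param truths Tibble of ground-truth rectangles with an `image_id`
#'   column.
#' @param n_images Number of images scored (defaults to the number of
#'   distinct `image_id` values across both tables).
#' @return List of class `mcc_score`: `sensitivity`, `fp_per_image`, `tp`,
#'   `fp`, `fn`, `n_images`, and a `per_image` tibble.
#' @export
score_image_set <- function(detections, truths, n_images = NULL) {
  ids <- union(unique(detections$image_id), unique(truths$image_id))
  if (is.null(n_images)) n_images <- length(ids)
  if (n_images == 0) abort("no images to score")
  per_image <- lapply(ids, function(im) {
    det <- detections[detections$image_id == im, , drop = FALSE]
    gt <- truths[truths$image_id == im, , drop = FALSE]
    nd <- nrow(det); ng <- nrow(gt)
    pairs <- NULL
    if (nd && ng) {
      pairs <- expand.grid(d = seq_len(nd), g = seq_len(ng))
      m <- Map(function(d, g) kallergi_match(det[d, ], gt[g, ]),
               pairs$d, pairs$g)
      pairs$tp <- vapply(m, `[[`, logical(1), "tp")
      pairs$ratio <- vapply(m, `[[`, numeric(1), "overlap_ratio")
      pairs <- pairs[pairs$tp, , drop = FALSE]
      pairs <- pairs[order(-pairs$ratio), , drop = FALSE]
    }
    used_d <- logical(nd); used_g <- logical(ng)
    tp <- 0L
    if (!is.null(pairs) && nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        d <- pairs$d[k]; g <- pairs$g[k]
        if (!used_d[d] && !used_g[g]) {
          used_d[d] <- used_g[g] <- TRUE
          tp <- tp + 1L
        }
      }
    }
    tibble(image_id = im, tp = tp, fp = nd - tp, fn = ng - tp)
  })
  per_image <- bind_rows(per_image)
  tp <- sum(per_image$tp); fp <- sum(per_image$fp); fn <- sum(per_image$fn)
  structure(
    list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
         fp_per_image = fp / n_images,
         tp = tp, fp = fp, fn = fn, n_images = n_images,
         per_image = per_image),
    class = "mcc_score"
  )
}

#' @export
print.mcc_score <- function(x, ...) {
  cat(sprintf(
    "<mcc_score> sensitivity %.3f, %.3f FP/image (TP %d, FP %d, FN %d over %d images)\n",
    x$sensitivity, x$fp_per_image, x$tp, x$fp, x$fn, x$n_images))
  invisible(x)
}

#' One-row summary of a detection score
#'
#' @param x An `mcc_score`.
#' @param ... Unused.
#' @return One-row tibble with sensitivity, FP/image and the raw counts.
#' @export
glance.mcc_score <- function(x, ...) {
  tibble(sensitivity = x$sensitivity, fp_per_image = x$fp_per_image,
         tp = x$tp, fp = x$fp, fn = x$fn, n_images = x$n_images)
}

#' Free-response ROC over the voting threshold
#'
#' For each `N` in 1..18 the candidate set is re-thresholded at vote sum
#' `>= N`, re-clustered per image and re-scored against the ground truth,
#' giving one (sensitivity, FP/image) point per threshold. Acceptance is
#' nested in `N`, so both coordinates are non-increasing in `N`.
#'
#' @param scored_candidates Tibble with one row per candidate: `image_id`,
#'   `vote_sum`, and the geometry columns used by [cluster_mcs()].
#' @param truths Tibble of ground-truth rectangles with `image_id`.
#' @param pixel_spacing_mm Pixel size in millimetres.
#' @param n_images Number of images (defaults to distinct ids).
#' @param n_max Largest threshold (default 18).
#' @return Tibble of class `froc_curve` with columns `N`, `sensitivity`,
#'   `fp_per_image`.
#' @export
froc_curve <- function(scored_candidates, truths, pixel_spacing_mm,
                       n_images = NULL, n_max = 18L) {
  ids <- union(unique(scored_candidates$image_id), unique(truths$image_id))
  if (is.null(n_images)) n_images <- length(ids)
  pts <- lapply(seq_len(n_max), function(nn) {
    acc <- scored_candidates[scored_candidates$vote_sum >= nn, , drop = FALSE]
    dets <- acc |>
      group_by(.data$image_id) |>
      dplyr::group_modify(~ cluster_mcs(.x, pixel_spacing_mm)) |>
      ungroup()
    sc <- score_image_set(dets, truths, n_images = n_images)
    tibble(N = nn, sensitivity = sc$sensitivity, fp_per_image = sc$fp_per_image)
  })
  structure(bind_rows(pts), class = c("froc_curve", class(tibble())))
}

#' Plot an fROC curve
#'
#' @param object A `froc_curve` tibble.
#' @param ... Unused.
#' @return A ggplot: sensitivity against FP/image, one point per voting
#'   threshold.
#' @export
autoplot.froc_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$fp_per_image, y = .data$sensitivity)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "False positives per image", y = "Sensitivity",
                  title = "Free-response ROC over the voting threshold N") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic of the scores (ties
#' contribute 1/2), which equals the trapezoidal area under the empirical
#' ROC.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (0/1), both classes present.
#' @return Az in `[0, 1]`.
#' @export
roc_az <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) abort("both classes must be present")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
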