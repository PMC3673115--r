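# End-to-end drivers: per-image processing (ILT -> breast mask -> filter
# bank -> count-controlled candidates -> knowledge rules -> texture
# features), ensemble training with automated feature selection, detection,
# and evaluation.

#' Process one mammogram up to labelled candidates and features
#'
#' Runs the deterministic front half of the pipeline: ILT transform, breast
#' region mask, the 18 feature images, the two count-controlled candidate
#' searches (top-hat and wavelet branches) combined by OR, the knowledge
#' rules, and the per-candidate 56-feature texture matrices.
#'
#' @param image A 14-bit [mammogram()].
#' @param config An [mcc_config()]; the physical-distance rules use the
#'   image's own pixel spacing.
#' @return List: `ilt`, `breast_mask`, `feature_images`, `candidates`
#'   (tibble after the knowledge rules), `feature_mats` (18 tibbles),
#'   `branch_counts` (top-hat and wavelet candidate counts) and
#'   `branch_in_range`.
#' @export
process_image <- function(image, config = mcc_config()) {
  stopifnot(inherits(image, "mammogram"))
  cfg <- config
  cfg$pixel_spacing_mm <- image$pixel_spacing_mm
  ilt <- ilt_transform(image)
  breast <- detect_breast_region(ilt)
  fis <- build_feature_images(ilt, cfg$tophat_radius_px)
  cm_t <- iterative_candidate_search(fis$TopHat, cfg$candidate_range_tophat,
                                     breast)
  cm_w <- iterative_candidate_search(fis$Wavelet, cfg$candidate_range_wavelet,
                                     breast)
  cm <- combine_masks(cm_t, cm_w, breast)
  cands <- apply_knowledge_rules(cm$candidates, cfg)
  cands$pixels <- NULL
  fm <- extract_feature_matrix(fis, cands, size = cfg$window_size,
                               levels = cfg$glcm_levels)
  list(
    ilt = ilt, breast_mask = breast, feature_images = fis,
    candidates = cands, feature_mats = fm,
    branch_counts = c(tophat = attr(cm_t, "count"),
                      wavelet = attr(cm_w, "count")),
    branch_in_range = c(tophat = attr(cm_t, "in_range"),
                        wavelet = attr(cm_w, "in_range"))
  )
}

#' Label candidates against ground-truth MC points
#'
#' A candidate is MC-present (label 1) when a ground-truth point falls inside
#' its bounding box expanded by `tol_px` pixels.
#'
#' @param candidates Candidate tibble.
#' @param truth A [ground_truth()].
#' @param tol_px Bounding-box expansion tolerance (default 2).
#' @return The tibble with a `label` column added.
#' @export
label_candidates_by_truth <- function(candidates, truth, tol_px = 2) {
  pts <- truth$mc_points
  if (nrow(candidates) == 0) {
    candidates$label <- numeric(0)
    return(candidates)
  }
  lab <- vapply(seq_len(nrow(candidates)), function(i) {
    if (nrow(pts) == 0) return(0)
    as.numeric(any(
      pts$row >= candidates$row0[i] - tol_px &
        pts$row <= candidates$row1[i] + tol_px &
        pts$col >= candidates$col0[i] - tol_px &
        pts$col <= candidates$col1[i] + tol_px
    ))
  }, numeric(1))
  candidates$label <- lab
  candidates
}

# Pool per-image feature matrices into 18 dataset-wide tibbles; candidates
# get globally unique ids and an image_id column.
pool_feature_mats <- function(processed, image_ids) {
  nms <- feature_image_names()
  pooled <- lapply(nms, function(nm) {
    bind_rows(lapply(seq_along(processed), function(i) {
      fm <- processed[[i]]$feature_mats[[nm]]
      if (nrow(fm)) {
        fm$image_id <- image_ids[i]
        fm$candidate_id <- paste(image_ids[i], fm$candidate_id, sep = ":")
      } else {
        fm$image_id <- character(0)
        fm$candidate_id <- character(0)
      }
      fm
    }))
  })
  names(pooled) <- nms
  structure(pooled, class = "feature_matrices")
}

pooled_candidates <- function(processed, image_ids) {
  bind_rows(lapply(seq_along(processed), function(i) {
    cd <- processed[[i]]$candidates
    if (nrow(cd)) {
      cd$image_id <- image_ids[i]
      cd$candidate_id <- paste(image_ids[i], cd$id, sep = ":")
    } else {
      cd$image_id <- character(0)
      cd$candidate_id <- character(0)
    }
    cd
  }))
}

truth_rects <- function(truths, image_ids) {
  bind_rows(lapply(seq_along(truths), function(i) {
    r <- truths[[i]]$mcc_rects
    r$image_id <- rep(image_ids[i], nrow(r))
    r
  }))
}

# Stratified row cap used to keep subset evaluation and grid search
# tractable on large candidate pools; preserves the class ratio.
cap_patterns <- function(data, max_patterns, seed) {
  if (nrow(data) <= max_patterns) return(data)
  frac <- max_patterns / nrow(data)
  keep <- with_seed(seed, {
    unlist(lapply(c(1, 0), function(cl) {
      idx <- which(data$label == cl)
      sort(sample(idx, max(2, round(length(idx) * frac))))
    }))
  })
  data[sort(keep), , drop = FALSE]
}

#' Train the full detection model on a set of mammograms
#'
#' Processes every training image, labels candidates against the ground
#' truth, runs per-feature-image automated feature selection, trains the
#' 18-SVM ensemble (5:1 sampling and grid search per member), computes the
#' training fROC over the voting threshold, and fixes `N` as the largest
#' sensitivity with fewer than one false positive per image (when the
#' configuration says `"auto"`).
#'
#' @param dataset List of `synthetic_mammogram` objects, or of lists with
#'   elements `image` and `truth`.
#' @param config An [mcc_config()].
#' @param selection_method `"fscore"` (default), `"sfs"`, `"sbs"`, or
#'   `"best"` (run all and keep the per-image winner).
#' @param max_eval_patterns Cap on the patterns used inside subset evaluation
#'   and grid search (stratified subsample; the final member SVMs are fitted
#'   on the full 5:1 samples).
#' @return List of class `mcc_model`: `ensemble`, `selections`,
#'   `train_froc`, `train_score`, `config`, `processing` summary tibble.
#' @export
mcc_train <- function(dataset, config = mcc_config(),
                      selection_method = c("fscore", "sfs", "sbs", "best"),
                      max_eval_patterns = 400L) {
  selection_method <- match.arg(selection_method)
  image_ids <- sprintf("train%03d", seq_along(dataset))
  processed <- lapply(dataset, function(d) {
    p <- process_image(d$image, config)
    p$candidates <- label_candidates_by_truth(p$candidates, d$truth)
    p$feature_mats <- lapply(p$feature_mats, function(fm) {
      fm$label <- p$candidates$label
      fm
    })
    p$feature_images <- NULL   # free memory; features already extracted
    p$ilt <- NULL
    p
  })
  pooled <- pool_feature_mats(processed, image_ids)
  cands <- pooled_candidates(processed, image_ids)

  # per-feature-image selection on a capped 5:1 sample
  selections <- bind_rows(lapply(seq_along(pooled), function(i) {
    nm <- names(pooled)[i]
    samp <- sample_training_sets(pooled[[nm]], ratio = config$normal_to_mc_ratio,
                                 seed = derive_seed(config$seed, i))
    samp <- cap_patterns(samp, max_eval_patterns,
                         derive_seed(config$seed, 200 + i))
    gs <- grid_search(samp, samp$label, folds = 5L,
                      seed = derive_seed(config$seed, 300 + i))
    args <- list(features = samp, labels = samp$label, source_image = nm,
                 folds = 5L, seed = derive_seed(config$seed, 400 + i),
                 log2_C = gs$log2_C, log2_sigma = gs$log2_sigma)
    res <- switch(selection_method,
      fscore = do.call(fscore_selection, args),
      sfs = do.call(sfs, args),
      sbs = do.call(sbs, args),
      best = {
        r <- do.call(select_optimal, args[setdiff(names(args), "eval_fn")])
        r[r$winner, setdiff(names(r), "winner")]
      })
    res
  }))

  ensemble <- train_ensemble(pooled, selections, seed = config$seed,
                             ratio = config$normal_to_mc_ratio,
                             max_grid_patterns = max_eval_patterns)
  votes <- ensemble_votes(ensemble, pooled)
  scored <- left_join(cands, votes[, c("candidate_id", "vote_sum")],
                      by = "candidate_id")
  tr_truths <- truth_rects(lapply(dataset, `[[`, "truth"), image_ids)
  froc <- froc_curve(scored, tr_truths,
                     pixel_spacing_mm = dataset[[1]]$image$pixel_spacing_mm,
                     n_images = length(dataset))
  ensemble$N <- if (identical(config$voting_threshold_N, "auto")) {
    choose_N(froc)
  } else {
    as.integer(config$voting_threshold_N)
  }
  at_n <- froc[froc$N == ensemble$N, ]
  processing <- tibble(
    image_id = image_ids,
    n_candidates = vapply(processed, function(p) nrow(p$candidates), integer(1)),
    n_mc = vapply(processed, function(p) sum(p$candidates$label), numeric(1)),
    count_tophat = vapply(processed, function(p) p$branch_counts[["tophat"]], numeric(1)),
    count_wavelet = vapply(processed, function(p) p$branch_counts[["wavelet"]], numeric(1))
  )
  structure(
    list(ensemble = ensemble, selections = selections, train_froc = froc,
         train_sensitivity = at_n$sensitivity, train_fp_per_image = at_n$fp_per_image,
         config = config, processing = processing),
    class = "mcc_model"
  )
}

#' @export
print.mcc_model <- function(x, ...) {
  cat(sprintf(
    "<mcc_model> 18 SVMs, N = %d; training sensitivity %.3f at %.3f FP/image\n",
    x$ensemble$N, x$train_sensitivity, x$train_fp_per_image))
  invisible(x)
}

#' Detect microcalcification clusters on one mammogram
#'
#' Runs the candidate front end, applies the trained ensemble, accepts
#' candidates with at least `N` votes, and groups the accepted spots into
#' cluster detections.
#'
#' @param model An `mcc_model` from [mcc_train()].
#' @param image A 14-bit [mammogram()].
#' @return List of class `mcc_detection`: `detections` (cluster rectangles),
#'   `candidates` (all post-rule candidates with `vote_sum`),
#'   `accepted` (candidates passing the vote threshold), `branch_counts`.
#' @export
mcc_detect <- function(model, image) {
  p <- process_image(image, model$config)
  votes <- ensemble_votes(model$ensemble, p$feature_mats)
  cands <- p$candidates
  cands$vote_sum <- votes$vote_sum[match(cands$id, votes$candidate_id)]
  acc <- cands[cands$vote_sum >= model$ensemble$N, , drop = FALSE]
  dets <- cluster_mcs(acc, pixel_spacing_mm = image$pixel_spacing_mm)
  structure(
    list(detections = dets, candidates = cands, accepted = acc,
         branch_counts = p$branch_counts),
    class = "mcc_detection"
  )
}

#' @export
print.mcc_detection <- function(x, ...) {
  cat(sprintf("<mcc_detection> %d cluster(s) from %d accepted of %d candidates\n",
              nrow(x$detections), nrow(x$accepted), nrow(x$candidates)))
  invisible(x)
}

#' Evaluate a trained model on a test set
#'
#' Processes every test image, applies the ensemble, and reports the fROC
#' over the voting threshold together with the operating point at the
#' model's chosen `N`.
#'
#' @param model An `mcc_model`.
#' @param dataset Test set in the same form as for [mcc_train()].
#' @return List of class `mcc_evaluation`: `score` (an `mcc_score` at the
#'   model's `N`), `froc` (a [froc_curve()] tibble), and `candidates`.
#' @export
mcc_evaluate <- function(model, dataset) {
  image_ids <- sprintf("test%03d", seq_along(dataset))
  processed <- lapply(dataset, function(d) {
    p <- process_image(d$image, model$config)
    p$feature_images <- NULL
    p$ilt <- NULL
    p
  })
  pooled <- pool_feature_mats(processed, image_ids)
  cands <- pooled_candidates(processed, image_ids)
  votes <- ensemble_votes(model$ensemble, pooled)
  scored <- left_join(cands, votes[, c("candidate_id", "vote_sum")],
                      by = "candidate_id")
  truths <- truth_rects(lapply(dataset, `[[`, "truth"), image_ids)
  spacing <- dataset[[1]]$image$pixel_spacing_mm
  froc <- froc_curve(scored, truths, pixel_spacing_mm = spacing,
                     n_images = length(dataset))
  acc <- scored[scored$vote_sum >= model$ensemble$N, , drop = FALSE]
  dets <- acc |>
    group_by(.data$image_id) |>
    dplyr::group_modify(~ cluster_mcs(.x, spacing)) |>
    ungroup()
  score <- score_image_set(dets, truths, n_images = length(dataset))
  structure(list(score = score, froc = froc, candidates = scored,
                 detections = dets),
            class = "mcc_evaluation")
}

#' @export
print.mcc_evaluation <- function(x, ...) {
  cat(sprintf("<mcc_evaluation> sensitivity %.3f at %.3f FP/image (N fixed)\n",
              x$score$sensitivity, x$score$fp_per_image))
  invisible(x)
}
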