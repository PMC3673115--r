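# RBF-SVM training: 5:1 negative sampling, (C, sigma) grid search under
# 5-fold cross-validation, the 18-member ensemble, and vote thresholding.

#' Radial basis function kernel
#'
#' `K(x, z) = exp(-sigma * ||x - z||^2)`, in `(0, 1]`.
#'
#' @param x,z Equal-length numeric vectors.
#' @param sigma Positive kernel width parameter (multiplies the squared
#'   distance).
#' @return A number in `(0, 1]`.
#' @export
#' @examples
#' rbf_kernel(c(0, 0), c(1, 0), 1)   # exp(-1)
rbf_kernel <- function(x, z, sigma) {
  if (length(x) != length(z)) abort("vectors differ in length")
  stopifnot(sigma > 0)
  exp(-sigma * sum((x - z)^2))
}

#' The (C, sigma) search grid
#'
#' `log2(C)` over the odd values -5, -3, ..., 15 and `log2(sigma)` over
#' -15, -13, ..., 3: 11 x 10 = 110 pairs.
#'
#' @return Tibble with columns `log2_C`, `log2_sigma`.
#' @export
svm_grid <- function() {
  g <- expand.grid(log2_sigma = seq(-15, 3, by = 2),
                   log2_C = seq(-5, 15, by = 2))
  as_tibble(g[, c("log2_C", "log2_sigma")])
}

# Stratified k-fold assignment, seeded; every fold gets members of each class
# when class counts allow.
stratified_folds <- function(labels, k, seed) {
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold_id
}

# Fit an RBF SVM with internal z-scoring (zero-variance columns pass through
# unscaled). Labels are coerced to a factor with levels c("1", "0") so the
# decision value is oriented toward the positive class. `tolerance` is the
# libsvm stopping tolerance: cross-validation screening fits use a looser
# value than final fits.
fit_rbf_svm <- function(x, labels, log2_C = 0, log2_sigma = -5,
                        tolerance = 0.001) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  y <- factor(labels, levels = c(1, 0))
  model <- e1071::svm(xs, y, type = "C-classification", kernel = "radial",
                      cost = 2^log2_C, gamma = 2^log2_sigma, scale = FALSE,
                      tolerance = tolerance)
  structure(list(model = model, center = ctr, scale = scl,
                 log2_C = log2_C, log2_sigma = log2_sigma),
            class = "rbf_svm_fit")
}

predict_rbf_svm <- function(fit, x) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  pr <- predict(fit$model, xs, decision.values = TRUE)
  score <- as.numeric(attr(pr, "decision.values"))
  # decision values are oriented toward the first factor level ("1")
  list(class = as.numeric(as.character(pr)), score = score)
}

#' Sample a 5:1 normal-to-MC training set
#'
#' Keeps every MC-present pattern and draws a seeded uniform sample of
#' MC-absent patterns of size `ratio` times the MC-present count. When fewer
#' normals are available, all of them are kept and a warning is emitted.
#'
#' @param data Tibble/data frame with a binary `label` column (1 = MC
#'   present).
#' @param ratio Normal-to-MC ratio (default 5).
#' @param seed Sampling seed.
#' @return The sampled rows (MC rows first), in stable order.
#' @export
sample_training_sets <- function(data, ratio = 5, seed = 1L) {
  if (!"label" %in% names(data)) abort("`data` needs a `label` column")
  pos <- which(data$label == 1)
  neg <- which(data$label == 0)
  if (length(pos) == 0 || length(neg) == 0) abort("both classes must be present")
  want <- round(ratio * length(pos))
  if (length(neg) < want) {
    warn(sprintf("only %d MC-absent patterns available (wanted %d); using all",
                 length(neg), want))
    take <- neg
  } else {
    take <- with_seed(seed, sort(sample(neg, want)))
  }
  data[c(pos, take), , drop = FALSE]
}

#' Grid search for the RBF-SVM parameters
#'
#' Evaluates every `(C, sigma)` pair of the grid by stratified k-fold
#' cross-validated misclassification error and returns the pair with the
#' lowest error; ties are broken toward smaller `C`, then smaller `sigma`.
#'
#' @param features Feature tibble or matrix.
#' @param labels Binary labels (0/1).
#' @param folds CV folds (default 5).
#' @param seed Seed fixing the fold assignment.
#' @param grid Tibble of `log2_C`, `log2_sigma` pairs (default [svm_grid()]).
#' @return List with `log2_C`, `log2_sigma`, `cv_error` and the full
#'   `cv_table` tibble.
#' @export
grid_search <- function(features, labels, folds = 5L, seed = 1L,
                        grid = svm_grid()) {
  x <- feature_matrix_of(features)
  if (length(unique(labels)) < 2) abort("grid search needs both classes")
  fold_id <- stratified_folds(labels, folds, seed)
  errs <- vapply(seq_len(nrow(grid)), function(i) {
    pred <- numeric(length(labels))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- fit_rbf_svm(x[tr, , drop = FALSE], labels[tr],
                         log2_C = grid$log2_C[i], log2_sigma = grid$log2_sigma[i],
                         tolerance = 0.01)
      pred[!tr] <- predict_rbf_svm(fit, x[!tr, , drop = FALSE])$class
    }
    mse(labels, pred)
  }, numeric(1))
  tab <- mutate(grid, cv_error = errs)
  ord <- order(tab$cv_error, tab$log2_C, tab$log2_sigma)
  best <- tab[ord[1], ]
  list(log2_C = best$log2_C, log2_sigma = best$log2_sigma,
       cv_error = best$cv_error, cv_table = tab)
}

#' Train the 18-SVM ensemble
#'
#' For each feature image: restrict the feature matrix to that image's
#' selected subset, draw the 5:1 training sample (per-member derived seed),
#' grid-search `(C, sigma)`, and fit the final SVM on the sampled set.
#'
#' @param feature_mats Named list of 18 feature tibbles (each with a `label`
#'   column), as from [extract_feature_matrix()] rows pooled over training
#'   images.
#' @param selections Named list mapping each feature-image name to its
#'   selected feature indices, or a selection tibble with `source_image` and
#'   `selected` columns (one winning row per image).
#' @param seed Master seed.
#' @param ratio Normal-to-MC sampling ratio (default 5).
#' @param folds CV folds for the grid search.
#' @param grid Parameter grid (default [svm_grid()]).
#' @param max_grid_patterns Cap on the patterns used by each member's grid
#'   search (stratified subsample; the final fit always uses the full 5:1
#'   sample). Default unlimited.
#' @return An `mcc_ensemble` with one member per feature image and voting
#'   threshold `N` unset (`NA`) until [choose_N()].
#' @export
train_ensemble <- function(feature_mats, selections, seed = 1L, ratio = 5,
                           folds = 5L, grid = svm_grid(),
                           max_grid_patterns = Inf) {
  nms <- names(feature_mats)
  sel_list <- if (is.data.frame(selections)) {
    stats::setNames(selections$selected, selections$source_image)
  } else {
    selections
  }
  if (!all(nms %in% names(sel_list))) {
    abort("`selections` must cover every feature image")
  }
  members <- lapply(seq_along(nms), function(i) {
    nm <- nms[i]
    fm <- feature_mats[[nm]]
    sub <- sort(unlist(sel_list[[nm]]))
    samp <- sample_training_sets(fm, ratio = ratio,
                                 seed = derive_seed(seed, i))
    x <- feature_matrix_of(samp)[, sub, drop = FALSE]
    y <- samp$label
    gsub <- cap_patterns(tibble(label = y, .row = seq_along(y)),
                         max_grid_patterns, derive_seed(seed, 500 + i))
    gs <- grid_search(x[gsub$.row, , drop = FALSE], y[gsub$.row],
                      folds = folds, seed = derive_seed(seed, 100 + i),
                      grid = grid)
    fit <- fit_rbf_svm(x, y, log2_C = gs$log2_C, log2_sigma = gs$log2_sigma)
    list(source_image = nm, features = sub, fit = fit,
         log2_C = gs$log2_C, log2_sigma = gs$log2_sigma,
         cv_error = gs$cv_error, n_train = nrow(samp))
  })
  names(members) <- nms
  structure(list(members = members, N = NA_integer_, seed = seed),
            class = "mcc_ensemble")
}

#' Per-candidate votes of the ensemble
#'
#' Applies each member SVM to its own feature image's matrix (restricted to
#' the member's selected features) and tallies the 18 binary votes per
#' candidate.
#'
#' @param model An `mcc_ensemble`.
#' @param feature_mats Named list of 18 feature tibbles aligned by row.
#' @return Tibble with `candidate_id`, the per-member vote columns (one per
#'   feature image), and `vote_sum`.
#' @export
ensemble_votes <- function(model, feature_mats) {
  nms <- names(model$members)
  n <- nrow(feature_mats[[1]])
  votes <- vapply(nms, function(nm) {
    m <- model$members[[nm]]
    x <- feature_matrix_of(feature_mats[[nm]])[, m$features, drop = FALSE]
    if (n == 0) numeric(0) else predict_rbf_svm(m$fit, x)$class
  }, numeric(n))
  if (n == 1) votes <- matrix(votes, nrow = 1, dimnames = list(NULL, nms))
  out <- as_tibble(votes)
  out$candidate_id <- feature_mats[[1]]$candidate_id
  out$vote_sum <- rowSums(votes)
  out[, c("candidate_id", nms, "vote_sum")]
}

#' Vote-threshold decision rule
#'
#' A candidate is accepted as a true microcalcification when at least `N` of
#' its 18 member votes are positive.
#'
#' @param votes Numeric vector of 18 binary votes.
#' @param N Threshold in 1..18.
#' @return Logical.
#' @export
ensemble_vote <- function(votes, N) {
  if (length(votes) != 18) abort("expected 18 votes")
  stopifnot(all(votes %in% c(0, 1)), N >= 1, N <= 18)
  sum(votes) >= N
}

#' Choose the voting threshold from a training fROC
#'
#' Among thresholds with fewer than `max_fp` false positives per image,
#' returns the one with the largest sensitivity (ties toward smaller `N`).
#' When no threshold satisfies the bound, `N = 18` is returned with a
#' warning.
#'
#' @param froc Tibble with columns `N`, `sensitivity`, `fp_per_image` (one
#'   row per threshold), as from [froc_curve()].
#' @param max_fp Strict FP/image bound (default 1).
#' @return Integer threshold.
#' @export
choose_N <- function(froc, max_fp = 1) {
  ok <- froc[froc$fp_per_image < max_fp, , drop = FALSE]
  if (nrow(ok) == 0) {
    warn(sprintf("no vote threshold achieves FP/image < %g; falling back to N = 18",
                 max_fp))
    return(18L)
  }
  ok <- ok[order(-ok$sensitivity, ok$N), ]
  as.integer(ok$N[1])
}

#' @export
print.mcc_ensemble <- function(x, ...) {
  cat(sprintf("<mcc_ensemble> %d members, voting threshold N = %s\n",
              length(x$members),
              if (is.na(x$N)) "unset" else x$N))
  invisible(x)
}

#' Per-member summary of a trained ensemble
#'
#' @param x An `mcc_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per member: source image, fitted `(C, sigma)`
#'   on the log2 scale, subset size, grid-search CV error and training-set
#'   size.
#' @export
tidy.mcc_ensemble <- function(x, ...) {
  bind_rows(lapply(x$members, function(m) {
    tibble(source_image = m$source_image, log2_C = m$log2_C,
           log2_sigma = m$log2_sigma, n_features = length(m$features),
           cv_error = m$cv_error, n_train = m$n_train)
  }))
}

#' One-row summary of a trained ensemble
#'
#' @param x An `mcc_ensemble`.
#' @param ... Unused.
#' @return One-row tibble: member count, voting threshold, mean CV error.
#' @export
glance.mcc_ensemble <- function(x, ...) {
  tibble(n_members = length(x$members), N = x$N,
         mean_cv_error = mean(vapply(x$members, `[[`, numeric(1), "cv_error")))
}
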