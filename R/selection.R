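# Automated feature-subset selection per feature image: sequential forward
# selection (SFS), sequential backward selection (SBS), and F-score-ranked
# prefixes, each scored by the 5-fold cross-validated mean squared label
# error of the RBF-SVM classifier; the subset with the minimum CV MSE wins.

#' Mean squared label error
#'
#' `MSE = mean((g - c)^2)`; for binary labels this equals the
#' misclassification rate.
#'
#' @param g Ground-truth labels (0/1).
#' @param c Classified labels (0/1).
#' @return A number in `[0, 1]` for binary labels.
#' @export
#' @examples
#' mse(c(1, 1, 0, 0), c(1, 0, 0, 0))   # 0.25
mse <- function(g, c) {
  if (length(g) != length(c)) abort("label vectors differ in length")
  if (length(g) == 0) abort("empty label vectors")
  mean((g - c)^2)
}

#' Two-class F-score of a feature column
#'
#' The ratio of the squared deviations of the class means from the overall
#' mean to the sum of the within-class variances:
#' \deqn{F = \frac{(\bar x^+ - \bar x)^2 + (\bar x^- - \bar x)^2}
#'            {\mathrm{var}^+ + \mathrm{var}^-}}
#' with sample variances (denominator `n_k - 1`). When both within-class
#' variances are zero a small epsilon keeps the score finite.
#'
#' @param x Numeric feature column.
#' @param labels Binary labels (0/1), both classes present.
#' @return Non-negative F-score.
#' @export
f_score <- function(x, labels) {
  pos <- x[labels == 1]; neg <- x[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) abort("both classes must be present")
  m <- mean(x)
  num <- (mean(pos) - m)^2 + (mean(neg) - m)^2
  den <- (if (length(pos) > 1) var(pos) else 0) +
    (if (length(neg) > 1) var(neg) else 0)
  if (den == 0) den <- 1e-12
  num / den
}

# Coerce a feature container (tibble with feature columns, or matrix) to a
# plain numeric matrix of the 56 (or p) feature columns.
feature_matrix_of <- function(features) {
  if (is.matrix(features)) return(features)
  df <- as.data.frame(features)
  df <- df[, setdiff(names(df), c("candidate_id", "label", "image_id",
                                  "source_image")), drop = FALSE]
  as.matrix(df)
}

#' Cross-validated evaluation of one feature subset
#'
#' Stratified 5-fold cross-validation of the RBF SVM on the given columns:
#' each fold's model is fitted on the remaining folds (features z-scored on
#' the training folds), the held-out fold contributes its squared label
#' error, and the pooled held-out decision scores give the ROC area.
#'
#' @param features Feature tibble or matrix.
#' @param labels Binary labels (0/1).
#' @param subset Integer column indices to use (non-empty).
#' @param folds Number of CV folds (default 5).
#' @param seed Seed fixing the fold assignment.
#' @param log2_C,log2_sigma RBF-SVM parameters (log2 scale).
#' @return List with `cv_mse` and `cv_az`.
#' @export
evaluate_subset <- function(features, labels, subset, folds = 5L, seed = 1L,
                            log2_C = 0, log2_sigma = -5) {
  if (length(subset) == 0) abort("empty feature subset")
  x <- feature_matrix_of(features)[, subset, drop = FALSE]
  fold_id <- stratified_folds(labels, folds, seed)
  pred <- numeric(length(labels))
  score <- numeric(length(labels))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- fit_rbf_svm(x[tr, , drop = FALSE], labels[tr],
                       log2_C = log2_C, log2_sigma = log2_sigma,
                       tolerance = 0.01)
    p <- predict_rbf_svm(fit, x[!tr, , drop = FALSE])
    pred[!tr] <- p$class
    score[!tr] <- p$score
  }
  list(cv_mse = mse(labels, pred), cv_az = roc_az(score, labels))
}

selection_result <- function(source_image, method, selected, cv_mse, cv_az) {
  k <- length(selected)
  tibble(
    source_image = source_image, method = method,
    selected = list(sort(selected)), n_features = k,
    cv_mse = cv_mse, cv_az = cv_az
  )
}

# Shared greedy driver: `step_fn(current)` proposes candidate subsets, the
# one with minimal cv MSE is taken (ties -> first proposal, i.e. lowest
# feature index). Returns the nested-family member with minimal MSE overall
# (ties -> higher Az, then fewer features).
greedy_search <- function(p, eval_fn, forward = TRUE) {
  current <- if (forward) integer() else seq_len(p)
  trace <- list()
  pool <- seq_len(p)
  while (if (forward) length(current) < p else length(current) > 1) {
    options <- if (forward) setdiff(pool, current) else current
    evals <- lapply(options, function(j) {
      cand <- if (forward) c(current, j) else setdiff(current, j)
      c(list(feature = j, subset = cand), eval_fn(cand))
    })
    best <- which.min(vapply(evals, `[[`, numeric(1), "cv_mse"))
    current <- evals[[best]]$subset
    trace[[length(trace) + 1]] <- evals[[best]]
  }
  if (!forward) {
    # include the starting full set in the evaluated family
    full <- c(list(feature = NA_integer_, subset = seq_len(p)),
              eval_fn(seq_len(p)))
    trace <- c(list(full), trace)
  }
  mses <- vapply(trace, `[[`, numeric(1), "cv_mse")
  azs <- vapply(trace, `[[`, numeric(1), "cv_az")
  sizes <- vapply(trace, function(t) length(t$subset), integer(1))
  ord <- order(mses, -azs, sizes)
  win <- trace[[ord[1]]]
  list(subset = win$subset, cv_mse = win$cv_mse, cv_az = win$cv_az,
       trace = trace)
}

#' Sequential forward selection
#'
#' Starts from the empty set and greedily adds the feature whose addition
#' minimizes the cross-validated MSE until all features are included; the
#' nested subset with the overall minimum CV MSE is returned (ties broken by
#' higher Az, then fewer features; within a step, by lowest feature index).
#'
#' @param features Feature tibble or matrix.
#' @param labels Binary labels (0/1).
#' @param eval_fn Function `(subset) -> list(cv_mse, cv_az)`; defaults to
#'   [evaluate_subset()] with the given `...` parameters.
#' @param source_image Name recorded in the result.
#' @param ... Passed to [evaluate_subset()] when `eval_fn` is NULL.
#' @return One-row selection tibble: `source_image`, `method`, `selected`
#'   (list column), `n_features`, `cv_mse`, `cv_az`.
#' @export
sfs <- function(features, labels, eval_fn = NULL, source_image = NA_character_,
                ...) {
  p <- ncol(feature_matrix_of(features))
  if (is.null(eval_fn)) {
    eval_fn <- function(s) evaluate_subset(features, labels, s, ...)
  }
  r <- greedy_search(p, eval_fn, forward = TRUE)
  selection_result(source_image, "SFS", r$subset, r$cv_mse, r$cv_az)
}

#' Sequential backward selection
#'
#' Starts from the complete feature set and greedily discards the feature
#' whose removal minimizes the cross-validated MSE; otherwise mirrors
#' [sfs()].
#'
#' @inheritParams sfs
#' @return One-row selection tibble.
#' @export
sbs <- function(features, labels, eval_fn = NULL, source_image = NA_character_,
                ...) {
  p <- ncol(feature_matrix_of(features))
  if (is.null(eval_fn)) {
    eval_fn <- function(s) evaluate_subset(features, labels, s, ...)
  }
  r <- greedy_search(p, eval_fn, forward = FALSE)
  selection_result(source_image, "SBS", r$subset, r$cv_mse, r$cv_az)
}

#' F-score-ranked prefix selection
#'
#' Ranks features by descending two-class F-score and evaluates the nested
#' prefixes of that ranking; the prefix with the minimum cross-validated MSE
#' is returned.
#'
#' @inheritParams sfs
#' @return One-row selection tibble.
#' @export
fscore_selection <- function(features, labels, eval_fn = NULL,
                             source_image = NA_character_, ...) {
  x <- feature_matrix_of(features)
  if (is.null(eval_fn)) {
    eval_fn <- function(s) evaluate_subset(features, labels, s, ...)
  }
  scores <- apply(x, 2, f_score, labels = labels)
  ranking <- order(scores, decreasing = TRUE)
  evals <- lapply(seq_along(ranking), function(k) {
    s <- ranking[seq_len(k)]
    c(list(subset = s), eval_fn(s))
  })
  mses <- vapply(evals, `[[`, numeric(1), "cv_mse")
  azs <- vapply(evals, `[[`, numeric(1), "cv_az")
  sizes <- vapply(evals, function(t) length(t$subset), integer(1))
  win <- evals[[order(mses, -azs, sizes)[1]]]
  selection_result(source_image, "F-score", win$subset, win$cv_mse, win$cv_az)
}

#' Run all selection methods and keep the winner
#'
#' Evaluates SFS, SBS, F-score prefixes and the ALL-features baseline on the
#' same cross-validation folds, then selects the overall winner by minimum
#' CV MSE (ties broken by higher Az, then fewer features).
#'
#' @inheritParams sfs
#' @param folds,seed,log2_C,log2_sigma Passed to [evaluate_subset()].
#' @return Tibble with one row per method; the winner is flagged in the
#'   logical `winner` column.
#' @export
select_optimal <- function(features, labels, source_image = NA_character_,
                           folds = 5L, seed = 1L, log2_C = 0, log2_sigma = -5) {
  eval_fn <- function(s) {
    evaluate_subset(features, labels, s, folds = folds, seed = seed,
                    log2_C = log2_C, log2_sigma = log2_sigma)
  }
  p <- ncol(feature_matrix_of(features))
  all_eval <- eval_fn(seq_len(p))
  res <- bind_rows(
    sfs(features, labels, eval_fn, source_image),
    sbs(features, labels, eval_fn, source_image),
    fscore_selection(features, labels, eval_fn, source_image),
    selection_result(source_image, "ALL", seq_len(p),
                     all_eval$cv_mse, all_eval$cv_az)
  )
  ord <- order(res$cv_mse, -res$cv_az, res$n_features)
  res$winner <- seq_len(nrow(res)) == ord[1]
  res
}
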