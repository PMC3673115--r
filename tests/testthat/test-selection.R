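# Small deterministic toy problems drive the selection machinery; the SVM
# evaluation itself is exercised through evaluate_subset.

toy_separable <- function(n = 30, p = 3, seed = 51) {
  withr::with_seed(seed, {
    labels <- rep(c(1, 0), each = n)
    x <- matrix(rnorm(2 * n * p), 2 * n, p)
    x[labels == 1, 1] <- x[labels == 1, 1] + 8   # feature 1 separates alone
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x, labels = labels)
  })
}

test_that("MSE equals the mean squared label difference", {
  expect_equal(mse(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0)
  expect_equal(mse(c(1, 1, 0, 0), c(1, 0, 0, 0)), 0.25)
  expect_equal(mse(c(1, 0, 1), c(0, 1, 0)), 1)
  expect_error(mse(1, c(1, 0)), "length")
  expect_error(mse(numeric(0), numeric(0)), "empty")
})

test_that("F-score measures two-class separation and matches a hand computation", {
  x <- c(10, 11, 12, 13, 14, 0, 1, 2, 3, 4)
  y <- rep(c(1, 0), each = 5)
  xb <- mean(x); xp <- mean(x[1:5]); xn <- mean(x[6:10])
  hand <- ((xp - xb)^2 + (xn - xb)^2) / (var(x[1:5]) + var(x[6:10]))
  expect_equal(f_score(x, y), hand)
  expect_equal(f_score(c(1, 2, 2, 1), c(1, 1, 0, 0)), 0)   # same class means
  # monotone in mean separation at fixed spread
  f1 <- f_score(c(rnorm(20, 0, 1e-3), rnorm(20, 1, 1e-3)), rep(c(0, 1), each = 20))
  f2 <- f_score(c(rnorm(20, 0, 1e-3), rnorm(20, 5, 1e-3)), rep(c(0, 1), each = 20))
  expect_gt(f2, f1)
  expect_error(f_score(1:5, rep(1, 5)), "classes")
})

test_that("subset evaluation is perfect on separable data, null on shuffled labels", {
  toy <- toy_separable()
  r <- evaluate_subset(toy$x, toy$labels, 1, seed = 1)
  expect_equal(r$cv_mse, 0)
  expect_equal(r$cv_az, 1)
  withr::with_seed(52, {
    shuffled <- sample(toy$labels)
  })
  rs <- evaluate_subset(toy$x, shuffled, 1:3, seed = 1)
  expect_lt(abs(rs$cv_az - 0.5), 0.2)
  # determinism under a fixed seed
  r2 <- evaluate_subset(toy$x, toy$labels, 1, seed = 1)
  expect_identical(r, r2)
})

test_that("SFS finds the single separating feature and matches a greedy oracle", {
  toy <- toy_separable()
  res <- sfs(toy$x, toy$labels, seed = 1)
  expect_equal(res$selected[[1]], 1L)
  expect_equal(res$cv_mse, 0)

  # independent greedy re-implementation on a 4-feature toy
  toy4 <- toy_separable(n = 20, p = 4, seed = 53)
  eval_fn <- function(s) evaluate_subset(toy4$x, toy4$labels, s, seed = 2)
  res4 <- sfs(toy4$x, toy4$labels, eval_fn)
  current <- integer(); best <- NULL
  for (step in 1:4) {
    opts <- setdiff(1:4, current)
    scores <- vapply(opts, function(j) eval_fn(c(current, j))$cv_mse, numeric(1))
    current <- c(current, opts[which.min(scores)])
    e <- eval_fn(current)
    if (is.null(best) || e$cv_mse < best$mse) best <- list(set = current, mse = e$cv_mse)
  }
  expect_equal(sort(res4$selected[[1]]), sort(best$set))
  expect_equal(res4$cv_mse, best$mse)
  full <- eval_fn(1:4)
  expect_lte(res4$cv_mse, full$cv_mse)
})

test_that("SBS discards a pure-noise feature first and beats the full set", {
  withr::with_seed(54, {
    labels <- rep(c(1, 0), each = 25)
    x <- cbind(rnorm(50) + 6 * labels, rnorm(50) + 5.5 * labels, rnorm(50))
  })
  eval_fn <- function(s) evaluate_subset(x, labels, s, seed = 3)
  res <- sbs(x, labels, eval_fn)
  expect_true(all(res$selected[[1]] %in% 1:2) || res$cv_mse == 0)
  expect_lte(res$cv_mse, eval_fn(1:3)$cv_mse)
  # greedy removal oracle for the first discarded feature
  removals <- vapply(1:3, function(j) eval_fn(setdiff(1:3, j))$cv_mse, numeric(1))
  first_removed <- which.min(removals)
  trace_first <- setdiff(1:3, sbs(x, labels, eval_fn)$selected[[1]])
  if (length(trace_first) == 1) expect_equal(trace_first, first_removed)
})

test_that("F-score selection evaluates prefixes of the F-score ranking", {
  toy <- toy_separable()
  res <- fscore_selection(toy$x, toy$labels, seed = 4)
  expect_equal(res$selected[[1]], 1L)
  expect_equal(res$cv_mse, 0)
  fs <- apply(toy$x, 2, f_score, labels = toy$labels)
  expect_equal(order(fs, decreasing = TRUE)[1], 1L)
})

test_that("select_optimal returns four methods and a winner with minimal MSE", {
  toy <- toy_separable(n = 15, p = 3)
  res <- select_optimal(toy$x, toy$labels, source_image = "ILT", seed = 5)
  expect_equal(nrow(res), 4)
  expect_setequal(res$method, c("SFS", "SBS", "F-score", "ALL"))
  expect_equal(sum(res$winner), 1)
  expect_equal(res$cv_mse[res$winner], min(res$cv_mse))
  expect_true(all(vapply(res$selected, length, integer(1)) >= 1))
})

test_that("every method's minimum MSE is bounded by the ALL-features MSE", {
  withr::with_seed(55, {
    labels <- rep(c(1, 0), each = 20)
    x <- cbind(rnorm(40) + 2 * labels, matrix(rnorm(40 * 3), 40, 3))
  })
  res <- select_optimal(x, labels, seed = 6)
  all_mse <- res$cv_mse[res$method == "ALL"]
  expect_true(all(res$cv_mse <= all_mse + 1e-12))
})
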