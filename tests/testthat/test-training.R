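test_that("RBF kernel matches its closed form and is symmetric", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 3), 1)
  expect_equal(rbf_kernel(0, 1, 1), exp(-1))
  withr::with_seed(61, {
    x <- rnorm(5); z <- rnorm(5); s <- runif(1, 0.1, 2)
  })
  expect_equal(rbf_kernel(x, z, s), rbf_kernel(z, x, s))
  expect_equal(rbf_kernel(x, z, s), exp(-s * sum((x - z)^2)))
  expect_error(rbf_kernel(1:2, 1:3, 1), "length")
})

test_that("the parameter grid covers the 110 stated (C, sigma) pairs", {
  g <- svm_grid()
  expect_equal(nrow(g), 110)
  expect_setequal(unique(g$log2_C), seq(-5, 15, by = 2))
  expect_setequal(unique(g$log2_sigma), seq(-15, 3, by = 2))
})

test_that("training sampler returns normals at five times the MC count", {
  withr::with_seed(62, {
    d <- tibble::tibble(x = rnorm(2100), label = rep(c(1, 0), c(100, 2000)))
  })
  s <- sample_training_sets(d, ratio = 5, seed = 9)
  expect_equal(sum(s$label == 1), 100)
  expect_equal(sum(s$label == 0), 500)
  expect_equal(nrow(s), 600)
  # determinism
  s2 <- sample_training_sets(d, ratio = 5, seed = 9)
  expect_identical(s, s2)
  expect_false(identical(s, sample_training_sets(d, ratio = 5, seed = 10)))
})

test_that("training sampler takes all normals and warns on shortfall", {
  d <- tibble::tibble(x = rnorm(400), label = rep(c(1, 0), c(100, 300)))
  expect_warning(s <- sample_training_sets(d, ratio = 5, seed = 1), "available")
  expect_equal(nrow(s), 400)
  expect_error(sample_training_sets(tibble::tibble(x = 1, label = 1)),
               "classes")
})

test_that("grid search attains zero CV error on a separable toy and is exhaustive-minimal", {
  withr::with_seed(63, {
    labels <- rep(c(1, 0), each = 20)
    x <- cbind(rnorm(40) + 10 * labels, rnorm(40))
  })
  sub_grid <- tidyr::expand_grid(log2_C = c(-1, 1, 3), log2_sigma = c(-5, -3, -1))
  gs <- grid_search(x, labels, seed = 2, grid = sub_grid)
  expect_equal(gs$cv_error, 0)
  # brute-force re-scan over the same sub-grid
  errs <- vapply(seq_len(nrow(sub_grid)), function(i) {
    fold_id <- mccdetect:::stratified_folds(labels, 5, 2)
    pred <- numeric(length(labels))
    for (f in 1:5) {
      tr <- fold_id != f
      fit <- mccdetect:::fit_rbf_svm(x[tr, , drop = FALSE], labels[tr],
                                     sub_grid$log2_C[i], sub_grid$log2_sigma[i])
      pred[!tr] <- mccdetect:::predict_rbf_svm(fit, x[!tr, , drop = FALSE])$class
    }
    mean((pred - labels)^2)
  }, numeric(1))
  expect_equal(gs$cv_error, min(errs))
  ord <- order(errs, sub_grid$log2_C, sub_grid$log2_sigma)
  expect_equal(c(gs$log2_C, gs$log2_sigma),
               c(sub_grid$log2_C[ord[1]], sub_grid$log2_sigma[ord[1]]))
  # determinism
  gs2 <- grid_search(x, labels, seed = 2, grid = sub_grid)
  expect_identical(gs$cv_table, gs2$cv_table)
})

test_that("the vote rule is an exact threshold on the vote sum", {
  v4 <- c(rep(1, 4), rep(0, 14))
  expect_true(ensemble_vote(v4, 4))
  expect_false(ensemble_vote(c(rep(1, 3), rep(0, 15)), 4))
  expect_true(ensemble_vote(c(1, rep(0, 17)), 1))
  expect_false(ensemble_vote(c(rep(1, 17), 0), 18))
  expect_true(ensemble_vote(rep(1, 18), 18))
  expect_error(ensemble_vote(c(1, 0), 1), "18")
})

test_that("the vote rule matches brute-force counting over random vote patterns", {
  withr::with_seed(64, {
    ok <- TRUE
    for (i in 1:10000) {
      votes <- rbinom(18, 1, runif(1))
      n <- sample(1:18, 1)
      if (ensemble_vote(votes, n) != (sum(votes) >= n)) ok <- FALSE
    }
  })
  expect_true(ok)
})

test_that("choose_N picks the largest sensitivity under one FP per image", {
  froc <- tibble::tibble(
    N = 1:18,
    sensitivity = seq(1, 0.15, length.out = 18),
    fp_per_image = c(3.4, 2.5, 1.4, 0.9, 0.7, rep(0.3, 13))
  )
  expect_equal(choose_N(froc), 4L)
  all_low <- dplyr::mutate(froc, fp_per_image = 0.5)
  expect_equal(choose_N(all_low), 1L)
  all_high <- dplyr::mutate(froc, fp_per_image = 2)
  expect_warning(n <- choose_N(all_high), "falling back")
  expect_equal(n, 18L)
})

test_that("a small ensemble trains end to end and votes sensibly", {
  toy <- generate_feature_toy(n_per_class = 25, n_informative = 3,
                              separation = 6, seed = 71)
  sels <- stats::setNames(rep(list(1:56), 18), names(toy$matrices))
  grid <- tidyr::expand_grid(log2_C = c(1, 5), log2_sigma = c(-9, -5))
  ens <- train_ensemble(toy$matrices, sels, seed = 3, ratio = 1, grid = grid)
  expect_s3_class(ens, "mcc_ensemble")
  expect_length(ens$members, 18)
  votes <- ensemble_votes(ens, toy$matrices)
  expect_equal(nrow(votes), 50)
  labels <- toy$matrices[[1]]$label
  # with huge separation nearly every member classifies nearly every pattern
  expect_gt(mean(votes$vote_sum[labels == 1]), 16)
  expect_lt(mean(votes$vote_sum[labels == 0]), 2)
  td <- tidy(ens)
  expect_equal(nrow(td), 18)
  expect_true(all(td$cv_error <= 0.5))
  # accepted sets are nested in N
  acc <- lapply(1:18, function(n) which(votes$vote_sum >= n))
  for (n in 2:18) expect_true(all(acc[[n]] %in% acc[[n - 1]]))
})
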