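test_that("MC clustering follows the three-member 1 cm single-linkage rule", {
  spacing <- 0.1   # 1 cm = 100 px
  trio <- dplyr::bind_rows(
    make_candidate(100, 100, id = 1L),
    make_candidate(130, 110, id = 2L),
    make_candidate(115, 140, id = 3L)
  )
  out <- cluster_mcs(trio, spacing)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_members, 3L)
  expect_setequal(out$member_ids[[1]], 1:3)
  # two spots never form a cluster
  expect_equal(nrow(cluster_mcs(trio[1:2, ], spacing)), 0)
  # two trios 5 cm apart stay separate
  far <- dplyr::bind_rows(trio, dplyr::mutate(trio, id = id + 3L,
                                              centroid_row = centroid_row + 500,
                                              row0 = row0 + 500L, row1 = row1 + 500L))
  expect_equal(nrow(cluster_mcs(far, spacing)), 2)
  expect_equal(nrow(cluster_mcs(trio[0, ], spacing)), 0)
})

test_that("cluster rectangles are tight bounding boxes over member pixels", {
  cands <- dplyr::bind_rows(
    rect_candidate(10, 20, 3, 3, id = 1L),
    rect_candidate(40, 50, 3, 3, id = 2L),
    rect_candidate(25, 35, 3, 3, id = 3L)
  )
  out <- cluster_mcs(cands, 0.1)
  expect_equal(c(out$row0, out$col0, out$row1, out$col1), c(10, 20, 42, 52))
})

test_that("Kallergi matching applies the 50% overlap and 4x area tests", {
  gt <- list(row0 = 10, col0 = 10, row1 = 29, col1 = 29)       # 400 px
  expect_true(kallergi_match(gt, gt)$tp)
  small <- list(row0 = 10, col0 = 10, row1 = 17, col1 = 29)    # 40% of gt
  m <- kallergi_match(small, gt)
  expect_false(m$tp)
  expect_equal(m$overlap_ratio, 0.4)
  huge <- list(row0 = 1, col0 = 1, row1 = 50, col1 = 50)       # covers, >4x
  expect_false(kallergi_match(huge, gt)$tp)
  ok4x <- list(row0 = 10, col0 = 10, row1 = 49, col1 = 49)     # exactly 4x
  expect_true(kallergi_match(ok4x, gt)$tp)
})

test_that("image-set scoring reproduces a hand-counted 3-image toy", {
  truths <- tibble::tibble(
    image_id = c("a", "b", "c"),
    row0 = 10, col0 = 10, row1 = 30, col1 = 30
  )
  detections <- tibble::tibble(
    image_id = c("a", "b", "b"),
    row0 = c(10, 100, 11), col0 = c(10, 100, 9),
    row1 = c(30, 120, 31), col1 = c(30, 120, 31)
  )
  sc <- score_image_set(detections, truths, n_images = 3)
  expect_equal(sc$tp, 2)    # a matched, b matched by second detection
  expect_equal(sc$fp, 1)    # the stray b detection
  expect_equal(sc$fn, 1)    # c missed
  expect_equal(sc$sensitivity, 2 / 3)
  expect_equal(sc$fp_per_image, 1 / 3)
  g <- glance(sc)
  expect_equal(g$sensitivity, 2 / 3)

  # no detections: zero sensitivity and zero FPs
  none <- score_image_set(detections[0, ], truths, n_images = 3)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$fp_per_image, 0)
  # perfect detections
  perfect <- score_image_set(truths, truths, n_images = 3)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fp_per_image, 0)
})

test_that("a failed-overlap detection counts as both FP and FN", {
  truths <- tibble::tibble(image_id = "a", row0 = 10, col0 = 10,
                           row1 = 29, col1 = 29)
  small <- tibble::tibble(image_id = "a", row0 = 10, col0 = 10,
                          row1 = 17, col1 = 29)   # 40% overlap
  sc <- score_image_set(small, truths, n_images = 1)
  expect_equal(c(sc$tp, sc$fp, sc$fn), c(0, 1, 1))
})

test_that("adding a spurious detection never helps", {
  truths <- tibble::tibble(image_id = "a", row0 = 10, col0 = 10,
                           row1 = 30, col1 = 30)
  good <- tibble::tibble(image_id = "a", row0 = 10, col0 = 10,
                         row1 = 30, col1 = 30)
  extra <- dplyr::bind_rows(good, tibble::tibble(image_id = "a", row0 = 200,
                                                 col0 = 200, row1 = 220,
                                                 col1 = 220))
  s1 <- score_image_set(good, truths, 1)
  s2 <- score_image_set(extra, truths, 1)
  expect_lte(s2$sensitivity, s1$sensitivity)
  expect_gte(s2$fp_per_image, s1$fp_per_image)
})

test_that("the fROC has 18 points with maximal sensitivity at N = 1 acceptance", {
  withr::with_seed(81, {
    cands <- dplyr::bind_rows(lapply(1:30, function(i) {
      r <- sample(20:280, 1); c <- sample(20:280, 1)
      cc <- make_candidate(r + 0:2, c + 0:2, id = i)
      cc$image_id <- sample(c("a", "b"), 1)
      cc$vote_sum <- sample(0:18, 1)
      cc
    }))
  })
  truths <- tibble::tibble(image_id = c("a", "b"), row0 = c(40, 100),
                           col0 = c(40, 100), row1 = c(90, 150),
                           col1 = c(90, 150))
  froc <- froc_curve(cands, truths, pixel_spacing_mm = 0.1, n_images = 2)
  expect_s3_class(froc, "froc_curve")
  expect_equal(froc$N, 1:18)
  expect_equal(max(froc$sensitivity), froc$sensitivity[1])
  p <- autoplot(froc)
  expect_s3_class(p, "ggplot")
})

test_that("ROC area equals the Mann-Whitney normalization and handles ties", {
  expect_equal(roc_az(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_az(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  withr::with_seed(82, {
    scores <- rnorm(10)
    labels <- rep(c(1, 0), each = 5)
  })
  pairs <- expand.grid(p = scores[labels == 1], n = scores[labels == 0])
  u <- mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n, 0.5, 0)))
  expect_equal(roc_az(scores, labels), u)
  # cross-check against pROC on a larger sample
  withr::with_seed(83, {
    s2 <- c(rnorm(40, 1), rnorm(40))
    l2 <- rep(c(1, 0), each = 40)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(l2, s2, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_az(s2, l2), ref, tolerance = 1e-12)
  expect_error(roc_az(1:3, c(1, 1, 1)), "classes")
})

test_that("null-model ROC area is near one half", {
  withr::with_seed(84, {
    az <- roc_az(rnorm(400), rep(c(1, 0), 200))
  })
  expect_lt(abs(az - 0.5), 0.1)
})
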