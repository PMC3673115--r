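test_that("threshold shift applies the piecewise mapping exactly", {
  expect_equal(threshold_shift(matrix(c(5, 10), 1), 7),
               matrix(c(0, 3), 1))
  x <- matrix(c(0, 3, 8, 12), 2, 2)
  expect_equal(threshold_shift(x, 0), x)            # T = 0 is the identity
  expect_equal(threshold_shift(x, 13), matrix(0, 2, 2))
  expect_error(threshold_shift(x, -1))
})

test_that("edge candidates recover disjoint bright disks and ignore flat images", {
  x <- matrix(0, 80, 80)
  for (ctr in list(c(20, 20), c(20, 60), c(60, 40))) {
    d2 <- outer((seq_len(80) - ctr[1])^2, (seq_len(80) - ctr[2])^2, "+")
    x[d2 <= 36] <- 100
  }
  m <- edge_candidates(x)
  expect_equal(mccdetect:::count_components(m), 3)
  expect_false(any(edge_candidates(matrix(0, 30, 30))))
})

test_that("a blob caught by only one edge operator still appears in the OR", {
  # Canny's hysteresis thresholds are relative to the global gradient
  # maximum, so a very bright disk blinds it to a much fainter one; the
  # Sobel threshold (4x the mean magnitude) stays low on a sparse image and
  # keeps the faint disk, which therefore reaches the OR through one
  # operator only
  x <- matrix(0, 90, 90)
  dA <- outer((seq_len(90) - 25)^2, (seq_len(90) - 25)^2, "+")
  x[dA <= 25] <- 4000
  dB <- outer((seq_len(90) - 65)^2, (seq_len(90) - 65)^2, "+")
  x[dB <= 25] <- 200
  faint <- dB <= 100
  sob <- mccdetect:::sobel_edges(x)
  can <- canny_edges(x)
  expect_true(any(sob & faint))           # Sobel keeps the faint disk
  expect_false(any(can & faint))          # Canny is blinded by the bright one
  m <- edge_candidates(x)
  expect_true(any(m & faint))             # and the OR keeps it
  expect_equal(mccdetect:::count_components(m), 2)
})

test_that("iterative search terminates immediately when already in range", {
  x <- matrix(0, 60, 60)
  for (ctr in list(c(15, 15), c(15, 45), c(45, 30))) {
    d2 <- outer((seq_len(60) - ctr[1])^2, (seq_len(60) - ctr[2])^2, "+")
    x[d2 <= 25] <- 100 + 10 * ctr[1]
  }
  cm <- iterative_candidate_search(x, c(1, 10))
  expect_true(attr(cm, "in_range"))
  expect_equal(nrow(cm$candidates), 3)
})

test_that("iterative search flags an unattainable count range", {
  x <- matrix(0, 40, 40)
  d2 <- outer((seq_len(40) - 20)^2, (seq_len(40) - 20)^2, "+")
  x[d2 <= 25] <- 100
  expect_warning(cm <- iterative_candidate_search(x, c(50, 60)), "not attained")
  expect_false(attr(cm, "in_range"))
})

test_that("thresholded foreground area is monotone non-increasing in T", {
  withr::with_seed(8, {
    x <- matrix(runif(400, 0, 100), 20, 20)
  })
  areas <- vapply(seq(0, 100, by = 5),
                  function(t) sum(threshold_shift(x, t) > 0), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("mask combination is an idempotent superset OR with relabelling", {
  a <- matrix(FALSE, 30, 30); a[5:8, 5:8] <- TRUE
  b <- matrix(FALSE, 30, 30); b[20:23, 20:23] <- TRUE
  ab <- combine_masks(a, b)
  expect_equal(nrow(ab$candidates), 2)           # disjoint: counts add
  expect_true(all(ab$mask[a | b]))               # superset of each input
  aa <- combine_masks(a, a)
  expect_equal(aa$mask, a)                       # OR idempotence
  ov <- matrix(FALSE, 30, 30); ov[7:10, 5:8] <- TRUE
  expect_equal(nrow(combine_masks(a, ov)$candidates), 1)  # overlap merges
  expect_error(combine_masks(a, matrix(FALSE, 10, 10)), "mismatch")
})

test_that("candidate tables carry consistent 8-connected geometry", {
  m <- matrix(FALSE, 20, 20)
  m[3:5, 3:5] <- TRUE
  m[6, 6] <- TRUE           # diagonal touch: same component under 8-conn
  m[15, 15] <- TRUE
  cm <- label_candidates(m)
  expect_equal(nrow(cm$candidates), 2)
  big <- cm$candidates[which.max(cm$candidates$area), ]
  expect_equal(big$area, 10L)
  expect_equal(big$delta_x, 4L)
  expect_equal(big$delta_y, 4L)
  expect_equal(sum(cm$candidates$area), sum(m))
})

test_that("candidates from a breast-masked search stay inside the mask", {
  sm <- cached_phantom()
  ilt <- ilt_transform(sm$image)
  bm <- detect_breast_region(ilt)
  th <- tophat_filter(ilt$pixels)
  cm <- iterative_candidate_search(th, c(450, 550), bm)
  expect_true(all(cm$mask[!bm] == FALSE))
  expect_true(all(unlist(cm$candidates$pixels) %in% which(bm)))
})
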