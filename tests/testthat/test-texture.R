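test_that("window extraction crops interiors and reflects at borders", {
  withr::with_seed(31, {
    x <- matrix(rnorm(100 * 100), 100, 100)
  })
  w <- extract_window(x, c(50, 50), 16)
  expect_equal(w, x[42:57, 42:57])
  wb <- extract_window(x, c(1, 1), 16)
  expect_identical(dim(wb), c(16L, 16L))
  expect_equal(wb[9:16, 9:16], x[1:8, 1:8])       # in-bounds part intact
  expect_equal(wb[8, 9:16], x[2, 1:8])            # whole-sample reflected row
  expect_equal(extract_window(matrix(7, 20, 20), c(3, 3)),
               matrix(7, 16, 16))
})

test_that("window quantization is min-max linear with constants at level 0", {
  q <- quantize_patch(matrix(c(0, 50, 100), 1), levels = 4)
  expect_equal(as.vector(q), c(0L, 2L, 3L))
  expect_equal(as.vector(quantize_patch(matrix(5, 3, 3), 64)), rep(0L, 9))
  withr::with_seed(32, {
    p <- matrix(runif(64), 8, 8)
  })
  q64 <- quantize_patch(p, 64)
  expect_true(all(q64 >= 0 & q64 <= 63))
  expect_equal(q64[which.max(p)], 63L)
})

test_that("GLCM matches hand counts and the brute-force pair-counting oracle", {
  patch <- rbind(c(0L, 0L), c(1L, 1L))
  g <- compute_glcm(patch, theta = 0, levels = 2)
  expect_equal(unclass(g)[1, 1], 0.5)   # (0,0) pair
  expect_equal(unclass(g)[2, 2], 0.5)   # (1,1) pair
  gc <- compute_glcm(matrix(2L, 4, 4), theta = 90, levels = 4)
  expect_equal(unclass(gc)[3, 3], 1)    # constant patch: single entry

  withr::with_seed(33, {
    p8 <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  })
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  for (th in names(offs)) {
    g <- compute_glcm(p8, theta = as.numeric(th), levels = 4)
    oracle <- glcm_oracle(p8, offs[[th]][1], offs[[th]][2], 4)
    expect_equal(unclass(g), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("GLCMs are normalized, symmetric, and rotate with the patch", {
  withr::with_seed(34, {
    p <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
  })
  for (th in glcm_angles()) {
    g <- unclass(compute_glcm(p, th, levels = 8))
    expect_equal(sum(g), 1)
    expect_equal(g, t(g))
  }
  # 90-degree rotation maps the 0-degree GLCM onto the 90-degree GLCM
  prot <- t(p)[, rev(seq_len(nrow(p)))]   # counterclockwise rotation
  g0 <- unclass(compute_glcm(p, 0, levels = 8))
  g90r <- unclass(compute_glcm(prot, 90, levels = 8))
  expect_equal(g0, g90r, ignore_attr = TRUE)
})

test_that("the 14 features match an independent double-sum oracle", {
  withr::with_seed(35, {
    p <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  })
  g <- compute_glcm(p, 45, levels = 4)
  expect_equal(haralick_features(g), haralick_oracle(unclass(g)),
               tolerance = 1e-12)
  # larger level count too
  withr::with_seed(36, {
    p2 <- matrix(sample(0:15, 144, replace = TRUE), 12, 12)
  })
  g2 <- compute_glcm(p2, 135, levels = 16)
  expect_equal(haralick_features(g2), haralick_oracle(unclass(g2)),
               tolerance = 1e-12)
})

test_that("degenerate and structured patches give the expected features", {
  g <- compute_glcm(matrix(0L, 6, 6), theta = 0, levels = 8)
  f <- haralick_features(g)
  expect_equal(f[["energy"]], 1)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["entropy"]], 0)
  # checkerboard: every horizontal pair differs by exactly one level
  chk <- outer(1:8, 1:8, function(r, c) as.integer((r + c) %% 2))
  fc <- haralick_features(compute_glcm(chk, 0, levels = 2))
  expect_equal(fc[["contrast"]], 1)
  expect_gte(min(fc[["entropy"]], fc[["homogeneity"]]), 0)
})

test_that("feature vectors have 56 finite values in feature-major order", {
  withr::with_seed(37, {
    img <- matrix(rnorm(60 * 60, 100, 20), 60, 60)
  })
  v <- texture_vector(img, c(30, 30))
  expect_length(v, 56)
  expect_true(all(is.finite(v)))
  expect_equal(names(v)[1:4], paste0("contrast_", c(0, 45, 90, 135)))
  expect_equal(v[["contrast_0"]],
               haralick_features(compute_glcm(
                 quantize_patch(extract_window(img, c(30, 30))), 0,
                 levels = 64))[["contrast"]])
  # all-zero window is finite too
  expect_true(all(is.finite(texture_vector(matrix(0, 40, 40), c(20, 20)))))
})

test_that("the compiled batch extractor agrees with the R reference path", {
  withr::with_seed(38, {
    img <- matrix(rnorm(80 * 70, 500, 80), 80, 70)
  })
  centers <- rbind(c(40, 35), c(1, 1), c(80, 70), c(8, 60))
  batch <- mccdetect:::glcm_features_batch(img, as.integer(centers[, 1]),
                                           as.integer(centers[, 2]), 16L, 64L)
  for (i in seq_len(nrow(centers))) {
    expect_equal(unname(batch[i, ]),
                 unname(texture_vector(img, centers[i, ])),
                 tolerance = 1e-8)
  }
})

test_that("extract_feature_matrix returns 18 aligned tibbles of 56 features", {
  img <- fixture_raw_image(n = 48)
  fis <- build_feature_images(ilt_transform(img))
  cands <- dplyr::bind_rows(make_candidate(20, 20, id = 1L),
                            make_candidate(30, 35, id = 2L))
  fm <- extract_feature_matrix(fis, cands)
  expect_named(fm, feature_image_names())
  for (m in fm) {
    expect_equal(nrow(m), 2)
    expect_equal(ncol(m), 57)   # candidate_id + 56 features
    expect_true(all(is.finite(as.matrix(m[, -1]))))
  }
  # identical windows give identical vectors
  cands2 <- dplyr::bind_rows(make_candidate(20, 20, id = 1L),
                             make_candidate(20, 20, id = 2L))
  fm2 <- extract_feature_matrix(fis, cands2)
  expect_equal(unlist(fm2$ILT[1, -1]), unlist(fm2$ILT[2, -1]))
})
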