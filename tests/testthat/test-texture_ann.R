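test_that("the Haar LL band averages 2x2 blocks and preserves constants", {
  expect_equal(haar_ll(matrix(0.5, 6, 6)), matrix(0.5, 3, 3))
  expect_equal(haar_ll(matrix(c(0, 2, 0, 2), 2, 2)), matrix(1, 1, 1))
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(haar_ll(cb), matrix(0.5, 4, 4))
  # odd dimensions pad by edge replication
  expect_equal(dim(haar_ll(matrix(1, 5, 7))), c(3, 4))
  expect_equal(haar_ll(matrix(2, 5, 7)), matrix(2, 3, 4))
  expect_error(haar_ll(matrix(1, 1, 5)), "at least 2")
})

test_that("the Laws mask set is the nine L3/E3/S3 outer products", {
  m <- laws_masks()
  expect_length(m, 9)
  expect_equal(names(m), c("L3L3", "L3E3", "L3S3", "E3L3", "E3E3", "E3S3",
                           "S3L3", "S3E3", "S3S3"))
  expect_equal(m$L3L3, outer(c(1, 2, 1), c(1, 2, 1)))
  # every mask with an E3 or S3 factor has zero sum; L3L3 sums to 16
  sums <- vapply(m, sum, numeric(1))
  expect_equal(unname(sums["L3L3"]), 16)
  expect_true(all(abs(sums[-1]) < 1e-12))
})

test_that("laws_convolve matches the nested-loop oracle and the closed forms", {
  masks <- laws_masks()
  # constant input: zero-sum masks give zero, L3L3 gives 16c
  const <- matrix(3.25, 6, 6)
  r <- laws_convolve(const, masks)
  expect_equal(r$L3E3, matrix(0, 6, 6))
  expect_equal(r$L3L3, matrix(16 * 3.25, 6, 6))
  # impulse response away from borders stamps the flipped kernel
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  ri <- laws_convolve(imp, masks)
  for (nm in names(masks)) {
    expect_equal(ri[[nm]][4:6, 4:6], masks[[nm]][3:1, 3:1],
                 label = paste("impulse", nm))
  }
  # random grids against the brute-force convolution
  set.seed(99)
  for (trial in 1:5) {
    x <- matrix(rnorm(64), 8, 8)
    rr <- laws_convolve(x, masks)
    for (nm in names(masks)) {
      expect_lt(max(abs(rr[[nm]] - oracle_conv2(x, masks[[nm]]))), 1e-10)
    }
  }
  expect_error(laws_convolve(matrix(c(1, NA, 1, 1), 2, 2)), "3 x 3")
  expect_error(laws_convolve(matrix(c(1, NA, rep(1, 14)), 4, 4)), "non-finite")
})

test_that("texture energy is the window mean of |F|", {
  expect_equal(texture_energy(matrix(0, 10, 10), n = 2), matrix(0, 10, 10))
  expect_equal(texture_energy(matrix(-3, 9, 9), n = 1), matrix(3, 9, 9))
  f <- matrix(0, 5, 5); f[3, 3] <- 25
  expect_equal(texture_energy(f, n = 2)[3, 3], 1.0)
  expect_true(all(texture_energy(matrix(rnorm(100), 10, 10), n = 2) >= 0))
  expect_error(texture_energy(matrix(1, 5, 5), n = 3), "half")
})

test_that("texture responses are translation-equivariant away from borders", {
  set.seed(4)
  x <- matrix(rnorm(30 * 30), 30, 30)
  shifted <- rbind(x[3:30, ], x[29:30, ])        # shift up by 2 rows
  r1 <- laws_convolve(x)$S3S3
  r2 <- laws_convolve(shifted)$S3S3
  expect_equal(r2[5:20, 5:25], r1[7:22, 5:25], tolerance = 1e-12)
  e1 <- texture_energy(r1, n = 2)
  e2 <- texture_energy(r2, n = 2)
  expect_equal(e2[7:18, 7:22], e1[9:20, 7:22], tolerance = 1e-12)
})

test_that("the feature stack has the documented layout", {
  img <- tiny_test_image(1)
  s9 <- assemble_pixel_features(img, use_dwt = FALSE, include_color = FALSE, n = 2)
  expect_equal(dim(s9$features), c(40, 40, 9))
  expect_equal(s9$names, paste0("energy_", names(laws_masks())))
  s12 <- assemble_pixel_features(img, use_dwt = TRUE, include_color = TRUE, n = 2)
  expect_equal(dim(s12$features), c(40, 40, 12))
  expect_equal(tail(s12$names, 3), c("R", "G", "B"))
  # energy channels are non-negative
  expect_true(all(s12$features[, , 1:9] >= 0))
})

test_that("the classifier separates separable features and is seeded", {
  set.seed(10)
  mk <- function(seed) {
    set.seed(seed)
    lab <- matrix(rbinom(400, 1, 0.5), 20, 20)
    f <- array(0, dim = c(20, 20, 2))
    f[, , 1] <- ifelse(lab == 1, rnorm(400, 1, 0.1), rnorm(400, -1, 0.1))
    f[, , 2] <- rnorm(400)
    list(stack = structure(list(features = f, names = c("a", "b"),
                                config = list()), class = "pixel_features"),
         mask = lab)
  }
  train <- lapply(1:3, mk)
  m <- train_pixel_classifier(lapply(train, `[[`, "stack"),
                              lapply(train, `[[`, "mask"),
                              hidden = 4, epochs = 100,
                              sample_per_class = 300, seed = 1)
  held <- mk(99)
  pr <- predict_segmentation(m, held$stack)
  expect_gte(mean((pr$probability >= 0.5) == (held$mask == 1)), 0.99)
  # identical features for both classes: chance-level accuracy
  mk0 <- function(seed) {
    set.seed(seed)
    lab <- matrix(rbinom(400, 1, 0.5), 20, 20)
    f <- array(rnorm(800), dim = c(20, 20, 2))
    list(stack = structure(list(features = f, names = c("a", "b"),
                                config = list()), class = "pixel_features"),
         mask = lab)
  }
  tr0 <- lapply(1:3, mk0)
  m0 <- train_pixel_classifier(lapply(tr0, `[[`, "stack"),
                               lapply(tr0, `[[`, "mask"),
                               hidden = 4, epochs = 50,
                               sample_per_class = 300, seed = 1)
  h0 <- mk0(77)
  p0 <- predict_segmentation(m0, h0$stack)
  expect_lt(abs(mean((p0$probability >= 0.5) == (h0$mask == 1)) - 0.5), 0.07)
  # identical seeds give identical weights
  m2 <- train_pixel_classifier(lapply(train, `[[`, "stack"),
                               lapply(train, `[[`, "mask"),
                               hidden = 4, epochs = 100,
                               sample_per_class = 300, seed = 1)
  expect_identical(m$wts, m2$wts)
  # single-class training data is rejected
  ones <- mk(1); ones$mask[] <- 1
  expect_error(train_pixel_classifier(list(ones$stack), list(ones$mask)),
               "both spike and background")
})

test_that("prediction thresholds probabilities at the model threshold", {
  img <- tiny_test_image(2)
  mask <- matrix(0L, 40, 40); mask[10:25, 10:25] <- 1L
  st <- assemble_pixel_features(img, use_dwt = FALSE, n = 2)
  m <- train_pixel_classifier(list(st), list(mask), hidden = 4, epochs = 60,
                              sample_per_class = 200, seed = 2)
  pr <- predict_segmentation(m, img)
  expect_true(all(pr$mask[pr$probability >= m$threshold] == 1))
  expect_true(all(pr$mask[pr$probability < m$threshold] == 0))
  # feature-layout mismatch is a contract error
  other <- assemble_pixel_features(img, use_dwt = FALSE, include_color = FALSE,
                                   n = 2)
  expect_error(predict_segmentation(m, other), "layout")
})

test_that("serialised models predict identically after a JSON round trip", {
  img <- tiny_test_image(3)
  mask <- matrix(0L, 40, 40); mask[10:25, 10:25] <- 1L
  st <- assemble_pixel_features(img, use_dwt = FALSE, n = 2)
  m <- train_pixel_classifier(list(st), list(mask), hidden = 4, epochs = 60,
                              sample_per_class = 200, seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_ann(m, f)
  m2 <- read_ann(f)
  p1 <- predict_segmentation(m, img)
  p2 <- predict_segmentation(m2, img)
  expect_equal(p2$probability, p1$probability, tolerance = 1e-12)
  expect_identical(p2$mask, p1$mask)
})
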