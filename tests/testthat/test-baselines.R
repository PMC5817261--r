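test_that("patch features are 54-dimensional with replicated borders", {
  d <- c(6, 6, 6)
  ct <- array(seq_len(prod(d)), d)     # ramp volume
  pet <- array(rev(seq_len(prod(d))), d)
  f <- patch_features(ct, pet, c(3, 3, 3), normalize = FALSE)
  expect_identical(ncol(f), 54L)

  # corner voxel: hand-enumerated edge-replicated neighbourhood
  f1 <- patch_features(ct, pet, c(1, 1, 1), normalize = FALSE)
  hand <- numeric(27)
  k <- 0
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1
    hand[k] <- ct[max(1 + dx, 1), max(1 + dy, 1), max(1 + dz, 1)]
  }
  expect_equal(as.numeric(f1[1, 1:27]), hand)

  # constant volumes give constant pre-normalisation features
  cc <- array(7, d)
  fc <- patch_features(cc, cc, rbind(c(2, 2, 2), c(5, 5, 5)),
                       normalize = FALSE)
  expect_true(all(fc == 7))
})

test_that("balanced training sets have the configured size and balance", {
  set.seed(2)
  d <- c(12, 12, 12)
  lab <- array(0L, d); lab[4:6, 4:6, 4:6] <- 1L
  vol <- list(ct = array(rnorm(prod(d)), d),
              pet = array(rnorm(prod(d)), d), labels = lab)
  cfg <- baseline_config(samples_per_class = 20L)
  ts <- sample_training_set(list(vol), seed = 1, config = cfg)
  expect_identical(nrow(ts$features), 40L)
  expect_equal(mean(ts$targets == "lesion"), 0.5)
  expect_identical(ts, sample_training_set(list(vol), seed = 1,
                                           config = cfg))

  # exactly as many lesion voxels as requested: each used once
  cfg27 <- baseline_config(samples_per_class = 27L)
  ts27 <- sample_training_set(list(vol), seed = 1, config = cfg27)
  pos <- ts27$features[ts27$targets == "lesion", ]
  expect_identical(nrow(unique(pos)), 27L)

  # more requested than available: replacement with a warning
  cfg50 <- baseline_config(samples_per_class = 50L)
  expect_warning(sample_training_set(list(vol), seed = 1, config = cfg50),
                 "replacement")

  # lesion-free volume skipped with a warning
  vol0 <- vol; vol0$labels <- array(0L, d)
  expect_warning(
    expect_error(sample_training_set(list(vol0), seed = 1, config = cfg),
                 "no volume"),
    "skipped")
})

test_that("all three classifiers separate toy blobs and PCA reduces to
          15 dimensions", {
  set.seed(5)
  n <- 120
  f <- rbind(matrix(rnorm(n * 54, mean = 2), n),
             matrix(rnorm(n * 54, mean = -2), n))
  y <- factor(rep(c("lesion", "nonlesion"), each = n),
              levels = c("nonlesion", "lesion"))
  for (method in c("rf", "knn", "svm")) {
    fit <- fit_baseline(f, y, method = method, seed = 3)
    expect_identical(fit$ndim, 15L)
    pred <- petlesion:::.predict_one(fit$fit, fit$train_x, method,
                                     fit$train_x, fit$train_y, fit$hyper)
    expect_equal(mean(pred == y), 1)
  }
  expect_error(fit_baseline(f, factor(rep("lesion", nrow(f)),
                                      levels = levels(y)),
                            method = "rf"), "both classes")
})

test_that("1-nearest-neighbour recalls its own training set perfectly", {
  set.seed(6)
  f <- matrix(rnorm(80 * 54), 80)
  y <- factor(rep(c("lesion", "nonlesion"), 40),
              levels = c("nonlesion", "lesion"))
  fit <- fit_baseline(f, y, method = "knn",
                      config = baseline_config(k_neighbors = 1L), seed = 1)
  pred <- petlesion:::.predict_one(fit$fit, fit$train_x, "knn",
                                   fit$train_x, fit$train_y, fit$hyper)
  expect_equal(mean(pred == y), 1)
})

test_that("baseline volume prediction reproduces a high-contrast blob and
          honours region masks", {
  set.seed(7)
  d <- c(16, 16, 16)
  lab <- array(0L, d); lab[5:11, 5:11, 5:11] <- 1L
  ct <- array(rnorm(prod(d), sd = 0.05), d) + lab * 4
  pet <- array(rnorm(prod(d), sd = 0.05), d) + lab * 4
  vol <- list(ct = ct, pet = pet, labels = lab)
  cfg <- baseline_config(samples_per_class = 150L)
  ts <- sample_training_set(list(vol), seed = 2, config = cfg)
  fit <- fit_baseline(ts$features, ts$targets, method = "rf",
                      config = cfg, seed = 2)
  mask <- predict_baseline(fit, ct, pet)
  expect_equal(dim(mask), d)
  expect_gt(dice_score(mask, lab), 90)

  region <- array(FALSE, d); region[1:7, , ] <- TRUE
  m2 <- predict_baseline(fit, ct, pet, region = region)
  expect_true(all(!m2[8:16, , ]))
})
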