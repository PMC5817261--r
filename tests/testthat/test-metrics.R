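test_that("Dice score handles identity, disjoint and counted cases", {
  a <- array(0L, c(4, 4, 4)); a[1:2, 1, 1] <- 1L
  expect_equal(dice_score(a, a), 100)
  b <- array(0L, c(4, 4, 4)); b[3:4, 4, 4] <- 1L
  expect_equal(dice_score(a, b), 0)
  # |A| = 4, |B| = 6, |A int B| = 2 -> 2*2/10 = 40%
  a2 <- array(0L, c(10, 1, 1)); a2[1:4] <- 1L
  b2 <- array(0L, c(10, 1, 1)); b2[3:8] <- 1L
  expect_equal(dice_score(a2, b2), 40)
  expect_equal(dice_score(b2, a2), 40) # symmetry
  z <- array(0L, c(3, 3, 3))
  expect_equal(dice_score(z, z), 100) # both empty by convention
  expect_error(dice_score(a, a2), "shape")
})

test_that("voxel confusion metrics match hand arithmetic and report
          undefined denominators as NA", {
  # TP=3, FP=1, FN=2, TN=4
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  truth <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  m <- voxel_confusion(pred, truth)
  expect_equal(m[["sensitivity"]], 60)
  expect_equal(m[["specificity"]], 80)
  expect_equal(m[["precision"]], 75)

  m2 <- voxel_confusion(truth, truth)
  expect_equal(unname(m2), c(100, 100, 100), ignore_attr = TRUE)

  m3 <- voxel_confusion(rep(0, 10), truth)
  expect_equal(m3[["sensitivity"]], 0)
  expect_true(is.na(m3[["precision"]]))
})

test_that("voxelwise metrics agree with brute-force loops on random
          masks", {
  set.seed(11)
  for (i in 1:200) {
    pred <- array(rbinom(12^3, 1, runif(1, 0.05, 0.5)), c(12, 12, 12))
    truth <- array(rbinom(12^3, 1, runif(1, 0.05, 0.5)), c(12, 12, 12))
    tp <- fp <- fn <- tn <- 0
    for (j in seq_along(pred)) {
      if (pred[j] && truth[j]) tp <- tp + 1
      else if (pred[j]) fp <- fp + 1
      else if (truth[j]) fn <- fn + 1
      else tn <- tn + 1
    }
    m <- voxel_confusion(pred, truth)
    cnt <- attr(m, "counts")
    expect_equal(unname(cnt), c(tp, fp, fn, tn), ignore_attr = TRUE)
    expect_equal(dice_score(pred, truth), 200 * tp / (2 * tp + fp + fn))
  }
})

test_that("lesionwise patch detection matches exhaustive enumeration", {
  # 20^3 volume, one 3^3 lesion: positivity depends on patch offset
  truth <- array(0L, c(20, 20, 20))
  truth[9:11, 9:11, 9:11] <- 1L
  set.seed(5)
  pred <- truth
  pred[sample(which(truth == 1), 10)] <- 0L # partial prediction
  pred[2, 2, 2] <- 1L                        # a stray false positive

  res <- lesionwise_detection(pred, truth, region = array(TRUE, dim(truth)),
                              margin = 0L)
  oc <- oracle_detection_patches(pred, truth, lo = c(1, 1, 1),
                                 hi = c(20, 20, 20))
  tp <- sum(oc$truth_pos & oc$pred_pos)
  fp <- sum(!oc$truth_pos & oc$pred_pos)
  fn <- sum(oc$truth_pos & !oc$pred_pos)
  tn <- sum(!oc$truth_pos & !oc$pred_pos)
  cnt <- attr(res, "counts")
  expect_equal(unname(cnt), c(tp, fp, fn, tn), ignore_attr = TRUE)

  # a 3^3 lesion never fills 10% of a 9^3 patch, so the identity and
  # empty-prediction checks use a larger lesion
  big <- array(0L, c(20, 20, 20))
  big[8:13, 8:13, 8:13] <- 1L
  expect_equal(lesionwise_detection(big, big)[["sensitivity"]], 100)
  empty <- array(0L, dim(big))
  expect_equal(lesionwise_detection(empty, big)[["sensitivity"]], 0)
})

test_that("adding correctly predicted lesion voxels never lowers
          lesionwise sensitivity", {
  set.seed(21)
  truth <- array(0L, c(24, 24, 24))
  truth[6:10, 6:10, 6:10] <- 1L
  truth[15:19, 15:19, 15:19] <- 1L
  pred <- array(0L, dim(truth))
  prev <- 0
  pos <- which(truth == 1)
  for (frac in c(0.1, 0.3, 0.6, 1.0)) {
    pred[pos[seq_len(floor(frac * length(pos)))]] <- 1L
    s <- lesionwise_detection(pred, truth)[["sensitivity"]]
    expect_gte(s, prev)
    prev <- s
  }
})

test_that("half-maximum segmentation recovers blob geometry", {
  d <- c(31, 31, 31)
  ctr <- c(16, 16, 16)
  fwhm <- 6
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  xs <- seq_len(d[1]) - ctr[1]
  blob <- exp(-outer(outer(xs^2, xs^2, `+`), xs^2, `+`) / (2 * sig^2))
  mask <- half_max_segment(blob, ctr, radius = 12)
  # analytic half-max radius of a Gaussian = FWHM / 2
  vol <- sum(mask)
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  expect_equal(r_eq, fwhm / 2, tolerance = 0.25)

  # uniform plateau: the whole connected plateau is returned
  plat <- array(0, c(20, 20, 20))
  plat[5:10, 5:10, 5:10] <- 1
  m2 <- half_max_segment(plat, c(7, 7, 7), radius = 15)
  expect_identical(sum(m2), sum(plat == 1))

  # two distant blobs: the unseeded one is excluded
  two <- array(0, c(40, 20, 20))
  two[6:8, 9:11, 9:11] <- 1
  two[30:32, 9:11, 9:11] <- 1
  m3 <- half_max_segment(two, c(7, 10, 10), radius = 15)
  expect_true(all(which(m3, arr.ind = TRUE)[, 1] < 20))

  expect_warning(mb <- half_max_segment(two, c(15, 15, 15), radius = 5),
                 "background")
  expect_true(all(!mb))
})

test_that("k-fold splits are balanced, exhaustive and deterministic", {
  ids <- paste0("p", 1:12)
  f <- kfold_split(ids, k = 3, seed = 4)
  expect_identical(unname(lengths(f)), c(4L, 4L, 4L))
  expect_setequal(unlist(f), ids)
  expect_identical(kfold_split(ids, k = 3, seed = 4), f)
  expect_false(identical(kfold_split(ids, k = 3, seed = 5), f))
  expect_error(kfold_split(ids[1:2], k = 3), "exceeds")
})
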