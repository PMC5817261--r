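test_that("CT-to-mu mapping anchors water, air and bone correctly", {
  expect_equal(hu_to_mu(0), 0.0096)
  expect_equal(hu_to_mu(-1000), 0)
  expect_equal(hu_to_mu(-2000), 0) # clamped below air
  # bone segment: declared slope 5.1e-6 per HU above water
  expect_equal(hu_to_mu(1000), 0.0096 + 1000 * 5.1e-6)
  expect_error(hu_to_mu(c(0, NA)), "finite")
})

test_that("forward projection is linear and matches the chord-length law", {
  g <- voxel_grid(c(64, 64, 8), spacing = 4)
  geom <- pet_geometry(g)
  zero <- array(0, g$shape)
  expect_true(all(forward_project(zero, NULL, geom)$data == 0))

  set.seed(1)
  a <- array(runif(prod(g$shape)), g$shape)
  b <- array(runif(prod(g$shape)), g$shape)
  mu <- array(0.005, g$shape)
  pa <- forward_project(a, mu, geom)$data
  pb <- forward_project(b, mu, geom)$data
  pab <- forward_project(a + b, mu, geom)$data
  expect_equal(pa + pb, pab, tolerance = 1e-10)

  # uniform disc, no attenuation: radial profile ~ 2*sqrt(R^2 - s^2)
  R <- 100
  xs <- (seq_len(64) - 32.5) * 4
  disc <- array(0, g$shape)
  rr <- outer(xs^2, xs^2, `+`)
  for (z in 1:8) disc[, , z] <- rr <= R^2
  prof <- forward_project(disc, NULL, geom)$data[, 1, 4]
  s <- (seq_len(geom$nbins) - 1 - (geom$nbins - 1) / 2) * geom$bin_width
  chord <- ifelse(abs(s) < R, 2 * sqrt(pmax(R^2 - s^2, 0)), 0)
  rms <- sqrt(mean((prof - chord)^2)) / max(chord)
  expect_lt(rms, 0.02)
})

test_that("projector and backprojector are exact adjoints", {
  g <- voxel_grid(c(24, 24, 16), spacing = 6)
  geom <- pet_geometry(g)
  set.seed(2)
  for (i in 1:3) {
    x <- rnorm(prod(g$shape[1:2]))
    y <- rnorm(geom$nbins * geom$nang)
    lhs <- sum(as.numeric(geom$A %*% x) * y)
    rhs <- sum(x * as.numeric(Matrix::crossprod(geom$A, y)))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("expectation composition hits the configured count budget exactly", {
  g <- voxel_grid(c(24, 24, 16), spacing = 6)
  geom <- pet_geometry(g)
  ph <- build_anatomy(g, seed = 5)
  trues <- forward_project(ph$activity, hu_to_mu(ph$ct), geom)
  comp <- compose_expectation(trues, acquisition_model())
  expect_equal(sum(comp$expectation$data), 1e6, tolerance = 1e-9)
  expect_equal(sum(comp$scatter), 3e5, tolerance = 1e-9)
  expect_equal(sum(comp$randoms), 3e5, tolerance = 1e-9)
  expect_equal(sum(comp$trues), 4e5, tolerance = 1e-9)

  m0 <- acquisition_model(scatter_fraction = 0, randoms_fraction = 0,
                          total_counts = 5e5)
  c0 <- compose_expectation(trues, m0)
  expect_equal(c0$expectation$data,
               trues$data * (5e5 / sum(trues$data)), tolerance = 1e-9)

  zero <- sinogram(array(0, dim(trues$data)), geom)
  expect_error(compose_expectation(zero), "zero")
})

test_that("Poisson noise has the right mean, variance and determinism", {
  g <- voxel_grid(c(24, 24, 16), spacing = 6)
  geom <- pet_geometry(g)
  zero <- sinogram(array(0, c(geom$nbins, geom$nang, 16)), geom)
  expect_true(all(add_poisson(zero, seed = 1)$data == 0))

  lam <- sinogram(array(4, c(geom$nbins, geom$nang, 2)), geom)
  expect_identical(add_poisson(lam, seed = 3)$data,
                   add_poisson(lam, seed = 3)$data)

  # totals across seeds: mean within 3 sigma of the expectation
  ph <- build_anatomy(g, seed = 5)
  comp <- compose_expectation(forward_project(ph$activity,
                                              hu_to_mu(ph$ct), geom))
  tot <- vapply(1:50, function(s)
    sum(add_poisson(comp$expectation, seed = s)$data), numeric(1))
  expect_lt(abs(mean(tot) - 1e6), 3 * sqrt(1e6))

  # per-bin variance tracks the expectation on a reduced instance
  small <- sinogram(array(rep(c(2, 6, 12), length.out = 90 * 160 * 1),
                          c(90, 160, 1)), geom)
  draws <- sapply(1:120, function(s) add_poisson(small, seed = s)$data[1:300])
  vr <- apply(draws, 1, var)
  ex <- small$data[1:300]
  expect_lt(abs(mean(vr / ex) - 1), 0.15)
})

test_that("MLEM is identity at 0 iterations, monotone, and solves a toy
          system at the ML optimum", {
  # forged 2-voxel / 2-bin system
  A <- Matrix::Matrix(matrix(c(1, 0.3, 0.2, 1), 2, 2), sparse = TRUE)
  geom <- structure(list(A = A, nbins = 2L, nang = 1L, bin_width = 1,
                         grid = list(shape = c(2L, 1L, 1L))),
                    class = "pet_geometry")
  y <- sinogram(array(c(7, 5), c(2, 1, 1)), geom)

  x0 <- mlem_reconstruct(y, NULL, geom, n_iter = 0L)
  expect_true(stats::sd(x0) == 0 && all(x0 > 0)) # flat start returned

  x <- mlem_reconstruct(y, NULL, geom, n_iter = 300L)
  # brute-force Poisson likelihood maximisation on a grid
  gr <- as.matrix(expand.grid(seq(0.05, 10, by = 0.05),
                              seq(0.05, 10, by = 0.05)))
  AP <- gr %*% t(as.matrix(A)) # expected counts for every grid point
  ll <- log(AP) %*% c(7, 5) - rowSums(AP)
  best <- gr[which.max(ll), ]
  expect_equal(as.numeric(x), as.numeric(best), tolerance = 0.05)
  expect_true(all(x >= 0))
  lls <- attr(x, "loglik")
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("a full simulated study has the specified sinogram geometry and
          recovers lesion contrast", {
  g <- voxel_grid(c(32, 32, 16), spacing = 6)
  geom <- pet_geometry(g)
  ph <- build_anatomy(g, seed = 4)
  st0 <- simulate_study(ph, seed = 8, geom = geom, n_iter = 10L)
  expect_identical(dim(st0$counts$data)[1:2], c(90L, 160L))
  expect_identical(dim(st0$counts$data)[3], g$shape[3])
  # lesion-free: no voxel wildly above the marrow-level background
  bone <- ph$labels == tissue_codes()[["bone"]]
  expect_lt(max(st0$recon), 5 * mean(st0$recon[bone]))

  cfg <- phantom_config()
  cfg$deform_amp <- 0
  les <- sample_lesions(ph, c(3, 3), seed = 2, config = cfg)
  les <- lapply(les, function(l) { l$uptake <- 10; l })
  ph2 <- apply_lesions(ph, les, config = cfg)
  st <- simulate_study(ph2, seed = 8, geom = geom, n_iter = 10L)
  lm <- ph2$labels == tissue_codes()[["lesion"]]
  bm <- ph2$labels == tissue_codes()[["bone"]]
  expect_gt(mean(st$recon[lm]), 2 * mean(st$recon[bm]))

  # determinism of the whole chain
  st2 <- simulate_study(ph2, seed = 8, geom = geom, n_iter = 10L)
  expect_identical(st$recon, st2$recon)
  expect_identical(st$counts$data, st2$counts$data)
})
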