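test_that("direct convolution kernels match the im2col + gemm reference", {
  set.seed(4)
  for (cfg in list(list(d = c(7, 6, 5), ci = 2, co = 3, s = 1),
                   list(d = c(8, 8, 8), ci = 3, co = 2, s = 2),
                   list(d = c(5, 9, 4), ci = 1, co = 4, s = 2))) {
    x <- array(rnorm(prod(cfg$d) * cfg$ci), c(cfg$d, cfg$ci))
    W <- matrix(rnorm(27 * cfg$ci * cfg$co), 27 * cfg$ci, cfg$co)
    b <- rnorm(cfg$co)
    y <- petlesion:::cpp_conv3_fwd(x, dim(x), W, b, cfg$s)
    col <- petlesion:::cpp_im2col3(x, dim(x), cfg$s)
    ref <- sweep(col %*% W, 2, b, `+`)
    dim(ref) <- dim(y)
    expect_equal(y, ref, tolerance = 1e-12)

    dy <- array(rnorm(length(y)), dim(y))
    dx <- petlesion:::cpp_conv3_bwd_data(dy, dim(x), W, cfg$s)
    dym <- matrix(dy, prod(dim(y)[1:3]), cfg$co)
    refdx <- petlesion:::cpp_col2im3(dym %*% t(W), dim(x), cfg$s)
    expect_equal(dx, refdx, tolerance = 1e-12)

    dW <- petlesion:::cpp_conv3_bwd_w(x, dim(x), dy, cfg$co, cfg$s)
    refdW <- crossprod(col, dym)
    expect_equal(unclass(dW), unclass(refdW), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(attr(dW, "db"), colSums(dym), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("V-Net output preserves spatial shape, including awkward dims", {
  m <- build_vnet(vnet_spec(depth = 3, in_channels = 2, base_width = 4),
                  seed = 1)
  x <- array(rnorm(16^3 * 2), c(16, 16, 16, 2))
  expect_identical(dim(vnet_forward(m, x)), c(16L, 16L, 16L))
  x2 <- array(rnorm(13 * 10 * 11 * 2), c(13, 10, 11, 2))
  expect_identical(dim(vnet_forward(m, x2)), c(13L, 10L, 11L))
  expect_error(vnet_forward(m, array(0, c(8, 8, 8, 3))), "channels")

  # constant input: finite logits, probabilities strictly inside (0, 1)
  xc <- array(1, c(12, 12, 12, 2))
  lg <- vnet_forward(m, xc)
  expect_true(all(is.finite(lg)))
  p <- 1 / (1 + exp(-lg))
  expect_true(all(p > 0 & p < 1))
})

test_that("parameter count matches the closed-form architecture count", {
  spec <- vnet_spec(depth = 3, in_channels = 2, base_width = 8)
  m <- build_vnet(spec, seed = 2)
  w <- spec$widths
  conv_p <- function(ci, co) 27 * ci * co + co
  expected <- conv_p(2, w[1]) +                        # enc 1
    conv_p(w[1], w[2]) + conv_p(w[2], w[2]) +          # down 1, enc 2
    conv_p(w[2], w[3]) + conv_p(w[3], w[3]) +          # down 2, enc 3
    (27 * w[2] * w[3] + w[2]) + conv_p(2 * w[2], w[2]) + # up 2, dec 2
    (27 * w[1] * w[2] + w[1]) + conv_p(2 * w[1], w[1]) + # up 1, dec 1
    conv_p(w[1], 1)                                    # head
  expect_identical(count_params(m), as.integer(expected))
})

test_that("the full network gradient matches finite differences", {
  set.seed(12)
  m <- build_vnet(vnet_spec(depth = 2, in_channels = 2, base_width = 2),
                  seed = 3)
  x <- array(rnorm(6^3 * 2), c(6, 6, 6, 2))
  t <- array(rbinom(6^3, 1, 0.3), c(6, 6, 6))
  w <- class_weights(t)
  fw <- vnet_forward(m, x, cache = TRUE)
  g <- vnet_backward(m, fw$cache,
                     petlesion:::wce_logit_grad(fw$logits, t, w))
  eps <- 1e-5
  probe <- function(get, set, gmat) {
    p <- get(m$params)
    i <- sample(length(p), 1)
    loss_at <- function(v) {
      mm <- m
      pp <- p; pp[i] <- v
      mm$params <- set(mm$params, pp)
      petlesion:::wce_from_logits(vnet_forward(mm, x), t, w)
    }
    fd <- (loss_at(p[i] + eps) - loss_at(p[i] - eps)) / (2 * eps)
    expect_lt(abs(gmat[i] - fd) / max(abs(fd), 1e-8), 1e-4)
  }
  probe(function(p) p$enc[[1]]$W,
        function(p, v) { p$enc[[1]]$W[] <- v; p }, g$enc[[1]]$dW)
  probe(function(p) p$down[[1]]$W,
        function(p, v) { p$down[[1]]$W[] <- v; p }, g$down[[1]]$dW)
  probe(function(p) p$up[[1]]$W,
        function(p, v) { p$up[[1]]$W[] <- v; p }, g$up[[1]]$dW)
  probe(function(p) p$dec[[1]]$W,
        function(p, v) { p$dec[[1]]$W[] <- v; p }, g$dec[[1]]$dW)
  probe(function(p) p$head$W,
        function(p, v) { p$head$W[] <- v; p }, g$head$dW)
  probe(function(p) p$enc[[2]]$b,
        function(p, v) { p$enc[[2]]$b[] <- v; p }, g$enc[[2]]$db)
})

test_that("the W-Net cascade has the specified stage structure", {
  w <- build_wnet(seed = 5)
  expect_identical(w$stage1$spec$depth, 5L)
  expect_identical(w$stage2$spec$depth, 3L)
  expect_identical(w$stage1$spec$in_channels, 1L)
  expect_identical(w$stage2$spec$in_channels, 3L)
  expect_error(build_wnet(vnet_spec(5, 2), vnet_spec(3, 3)), "CT channel")
  expect_error(build_wnet(vnet_spec(5, 1), vnet_spec(3, 2)), "mask")
})

test_that("the stage-1 mask channel is informative for stage 2", {
  w <- build_wnet(vnet_spec(5, 1, base_width = 2),
                  vnet_spec(3, 3, base_width = 2), seed = 6)
  set.seed(6)
  d <- c(12, 12, 12)
  x <- array(rnorm(prod(d) * 3), c(d, 3))
  y1 <- vnet_forward(w$stage2, x)
  x0 <- x
  x0[, , , 3] <- 0
  y0 <- vnet_forward(w$stage2, x0)
  expect_gt(max(abs(y1 - y0)), 1e-6)
})
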