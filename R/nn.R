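#' Network architecture specification
#'
#' An encoder--decoder ("V") volumetric network: `depth` resolution
#' stages, 3x3x3 same-padded convolutions, stride-2 downsampling on the
#' compression path and stride-2 transposed convolutions on the
#' decompression path, with skip concatenations from each compression
#' stage to its mirror. Feature width doubles per stage from `base_width`
#' up to `width_cap`. The voxelwise output is a single foreground logit;
#' output spatial shape always equals input spatial shape.
#'
#' @param depth number of resolution stages (single net: 3; cascade: 5
#'   then 3).
#' @param in_channels input channels (CT only: 1; CT+PET: 2;
#'   CT+PET+mask: 3).
#' @param base_width feature maps at the finest stage (default 16).
#' @param width_cap maximum feature maps per stage (default 128).
#' @return An object of class `vnet_spec`.
#' @export
vnet_spec <- function(depth = 3L, in_channels = 2L, base_width = 16L,
                      width_cap = 128L) {
  if (depth < 2L) stop("depth must be >= 2")
  widths <- pmin(base_width * 2^(seq_len(depth) - 1L), width_cap)
  structure(list(depth = as.integer(depth),
                 in_channels = as.integer(in_channels),
                 base_width = as.integer(base_width),
                 width_cap = as.integer(width_cap),
                 widths = as.integer(widths)),
            class = "vnet_spec")
}

.he_init <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))

.new_conv <- function(cin, cout) {
  list(W = matrix(.he_init(27 * cin, 27 * cin * cout), 27 * cin, cout),
       b = numeric(cout))
}

.lrelu_alpha <- 0.01
.lrelu <- function(x) x * (.lrelu_alpha + (1 - .lrelu_alpha) * (x > 0))
.lrelu_bwd <- function(y, dy)
  dy * (.lrelu_alpha + (1 - .lrelu_alpha) * (y > 0))

#' Build a V-Net model
#'
#' Initialises all convolution kernels (He initialisation) for the
#' architecture described by a [vnet_spec()]. Deterministic given the
#' seed.
#'
#' @param spec a [vnet_spec()].
#' @param seed integer seed for weight initialisation.
#' @return An object of class `vnet` holding the parameter list.
#' @export
build_vnet <- function(spec, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  D <- spec$depth; w <- spec$widths
  params <- list()
  params$enc <- vector("list", D)
  params$enc[[1]] <- .new_conv(spec$in_channels, w[1])
  params$down <- vector("list", D - 1)
  params$up <- vector("list", D - 1)
  params$dec <- vector("list", D - 1)
  for (l in seq_len(D - 1)) {
    params$down[[l]] <- .new_conv(w[l], w[l + 1])
    params$enc[[l + 1]] <- .new_conv(w[l + 1], w[l + 1])
    # transposed conv fine<-coarse: kernel indexed over fine channels
    params$up[[l]] <- .new_conv_t(w[l], w[l + 1])
    params$dec[[l]] <- .new_conv(2L * w[l], w[l])
  }
  params$head <- .new_conv(w[1], 1L)
  structure(list(spec = spec, params = params, trained = FALSE),
            class = "vnet")
}

# transposed-conv parameters: W is (27*c_fine) x c_coarse
.new_conv_t <- function(c_fine, c_coarse) {
  list(W = matrix(.he_init(27 * c_coarse / 8, 27 * c_fine * c_coarse),
                  27 * c_fine, c_coarse),
       b = numeric(c_fine))
}

#' Number of trainable parameters of a model
#' @param model a `vnet` or `wnet`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  if (inherits(model, "wnet"))
    return(count_params(model$stage1) + count_params(model$stage2))
  n <- 0L
  walk <- function(p) {
    if (is.numeric(p)) n <<- n + length(p)
    else for (q in p) walk(q)
  }
  walk(model$params)
  n
}

# ---- layer primitives -----------------------------------------------------

.conv_fwd <- function(layer, x, stride = 1L) {
  cpp_conv3_fwd(x, as.integer(dim(x)), layer$W, layer$b,
                as.integer(stride))
}

.conv_bwd <- function(layer, x, dy, stride = 1L, need_dx = TRUE) {
  d <- as.integer(dim(x))
  dW <- cpp_conv3_bwd_w(x, d, dy, ncol(layer$W), as.integer(stride))
  db <- attr(dW, "db")
  attr(dW, "db") <- NULL
  dx <- NULL
  if (need_dx) dx <- cpp_conv3_bwd_data(dy, d, layer$W, as.integer(stride))
  list(dW = dW, db = db, dx = dx)
}

# transposed conv: coarse (cx) -> fine grid of dims fine_d (spatial triple)
.tconv_fwd <- function(layer, cx, fine_d) {
  cf <- length(layer$b)
  y <- cpp_conv3_bwd_data(cx, as.integer(c(fine_d, cf)), layer$W, 2L)
  sweep(y, 4, layer$b, `+`)
}

.tconv_bwd <- function(layer, cx, dy) {
  fd <- as.integer(dim(dy))
  dW <- cpp_conv3_bwd_w(dy, fd, cx, ncol(layer$W), 2L)
  attr(dW, "db") <- NULL
  db <- as.numeric(colSums(matrix(dy, prod(fd[1:3]), fd[4])))
  dcx <- cpp_conv3_fwd(dy, fd, layer$W, numeric(ncol(layer$W)), 2L)
  list(dW = dW, db = db, dx = dcx)
}

.concat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# ---- forward / backward over the whole network ----------------------------

.as_input <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

#' Forward pass of a V-Net
#'
#' @param model a `vnet`.
#' @param x input array `(nx, ny, nz, in_channels)` (a 3D array is taken
#'   as one channel).
#' @param cache keep intermediate activations for [vnet_backward()]?
#' @return Logit array `(nx, ny, nz)`; with `cache = TRUE`, a list
#'   `(logits, cache)`.
#' @export
vnet_forward <- function(model, x, cache = FALSE) {
  p <- model$params
  D <- model$spec$depth
  x <- .as_input(x)
  if (dim(x)[4] != model$spec$in_channels)
    stop(sprintf("expected %d input channels, got %d",
                 model$spec$in_channels, dim(x)[4]))
  e <- vector("list", D); dpre <- vector("list", D)
  e[[1]] <- .lrelu(.conv_fwd(p$enc[[1]], x))
  for (l in 2:D) {
    dpre[[l]] <- .lrelu(.conv_fwd(p$down[[l - 1]], e[[l - 1]], stride = 2L))
    e[[l]] <- .lrelu(.conv_fwd(p$enc[[l]], dpre[[l]]))
  }
  h <- e[[D]]
  u <- vector("list", D - 1); cc <- vector("list", D - 1)
  hh <- vector("list", D - 1)
  for (l in seq.int(D - 1, 1)) {
    u[[l]] <- .lrelu(.tconv_fwd(p$up[[l]], h, dim(e[[l]])[1:3]))
    cc[[l]] <- .concat4(u[[l]], e[[l]])
    h <- .lrelu(.conv_fwd(p$dec[[l]], cc[[l]]))
    hh[[l]] <- h
  }
  logits <- .conv_fwd(p$head, h)
  dim(logits) <- dim(logits)[1:3]
  if (!cache) return(logits)
  list(logits = logits,
       cache = list(x = x, e = e, dpre = dpre, u = u, cc = cc, hh = hh))
}

#' Backward pass of a V-Net
#'
#' @param model a `vnet`.
#' @param cache activation cache from `vnet_forward(..., cache = TRUE)`.
#' @param dlogits gradient of the loss w.r.t. the logits (3D array).
#' @return Gradient list with the same structure as `model$params`.
#' @export
vnet_backward <- function(model, cache, dlogits) {
  .vnet_backward_impl(model, cache, dlogits)
}

.vnet_backward_impl <- function(model, cache, dlogits) {
  p <- model$params
  D <- model$spec$depth
  g <- list(enc = vector("list", D), down = vector("list", D - 1),
            up = vector("list", D - 1), dec = vector("list", D - 1))
  dl <- dlogits
  dim(dl) <- c(dim(dlogits), 1L)

  bw <- .conv_bwd(p$head, cache$hh[[1]], dl)
  g$head <- list(dW = bw$dW, db = bw$db)
  dh <- bw$dx
  de_extra <- vector("list", D) # skip gradients accumulated per level
  for (l in seq_len(D - 1)) {
    dh <- .lrelu_bwd(cache$hh[[l]], dh)
    bw <- .conv_bwd(p$dec[[l]], cache$cc[[l]], dh)
    g$dec[[l]] <- list(dW = bw$dW, db = bw$db)
    wl <- dim(cache$u[[l]])[4]
    du <- .lrelu_bwd(cache$u[[l]], bw$dx[, , , seq_len(wl), drop = FALSE])
    de_extra[[l]] <- bw$dx[, , , wl + seq_len(wl), drop = FALSE]
    upin <- if (l == D - 1) cache$e[[D]] else cache$hh[[l + 1]]
    bwt <- .tconv_bwd(p$up[[l]], upin, du)
    g$up[[l]] <- list(dW = bwt$dW, db = bwt$db)
    dh <- bwt$dx
  }
  # dh now carries the gradient at e[[D]] coming through up[[D-1]]
  de <- dh
  for (l in seq.int(D, 2)) {
    if (l < D && !is.null(de_extra[[l]])) de <- de + de_extra[[l]]
    de <- .lrelu_bwd(cache$e[[l]], de)
    bw <- .conv_bwd(p$enc[[l]], cache$dpre[[l]], de)
    g$enc[[l]] <- list(dW = bw$dW, db = bw$db)
    dd <- .lrelu_bwd(cache$dpre[[l]], bw$dx)
    bw <- .conv_bwd(p$down[[l - 1]], cache$e[[l - 1]], dd, stride = 2L)
    g$down[[l - 1]] <- list(dW = bw$dW, db = bw$db)
    de <- bw$dx
  }
  de <- de + de_extra[[1]]
  de <- .lrelu_bwd(cache$e[[1]], de)
  bw <- .conv_bwd(p$enc[[1]], cache$x, de, need_dx = FALSE)
  g$enc[[1]] <- list(dW = bw$dW, db = bw$db)
  g
}

#' @export
print.vnet <- function(x, ...) {
  cat(sprintf("vnet: depth %d, in_channels %d, widths %s, %d parameters%s\n",
              x$spec$depth, x$spec$in_channels,
              paste(x$spec$widths, collapse = "-"), count_params(x),
              if (isTRUE(x$trained)) " (trained)" else ""))
  invisible(x)
}

#' Build a cascaded W-Net model
#'
#' Two V-Nets in sequence: stage 1 (default depth 5) segments the
#' skeleton from the CT channel alone; stage 2 (default depth 3) receives
#' CT, PET and the binarised stage-1 mask as three channels and predicts
#' the lesion probability. The stages are trained sequentially and stage 1
#' is frozen while stage 2 trains.
#'
#' @param spec1 [vnet_spec()] for the skeleton stage (in_channels must
#'   be 1).
#' @param spec2 [vnet_spec()] for the lesion stage (in_channels must
#'   be 3).
#' @param seed integer seed for weight initialisation.
#' @param threshold stage-1 mask binarisation threshold (default 0.5).
#' @return An object of class `wnet`.
#' @export
build_wnet <- function(spec1 = vnet_spec(depth = 5L, in_channels = 1L),
                       spec2 = vnet_spec(depth = 3L, in_channels = 3L),
                       seed = 1L, threshold = 0.5) {
  if (spec1$in_channels != 1L)
    stop("stage 1 takes the CT channel only (in_channels = 1)")
  if (spec2$in_channels != 3L)
    stop("stage 2 takes CT + PET + bone mask (in_channels = 3)")
  structure(list(stage1 = build_vnet(spec1, seed = derive_seed(seed, 11L)),
                 stage2 = build_vnet(spec2, seed = derive_seed(seed, 12L)),
                 threshold = threshold),
            class = "wnet")
}

#' @export
print.wnet <- function(x, ...) {
  cat("wnet cascade:\n  stage 1 (skeleton): ")
  print(x$stage1)
  cat("  stage 2 (lesion):   ")
  print(x$stage2)
  invisible(x)
}
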