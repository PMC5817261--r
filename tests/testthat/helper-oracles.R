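# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (scalar loops, exhaustive enumeration) so they share
# no code path with the implementation they check.

# Eq.-style weighted cross-entropy by scalar loop
oracle_wce <- function(pred, truth, weights, eps = 1e-7) {
  s <- 0
  for (i in seq_along(pred)) {
    p <- min(max(pred[i], eps), 1 - eps)
    w <- if (truth[i] == 1) weights[2] else weights[1]
    s <- s + w * (truth[i] * log(p) + (1 - truth[i]) * log(1 - p))
  }
  -s / length(pred)
}

# flood fill over the 26-neighbourhood; returns the number of connected
# components.  Pads the mask with an empty border so linear-index offsets
# cannot wrap, then grows frontiers vectorised.
oracle_n_components26 <- function(mask) {
  d <- dim(mask)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  dp <- dim(p)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  loff <- offs[, 1] + dp[1] * offs[, 2] + dp[1] * dp[2] * offs[, 3]
  visited <- array(FALSE, dp)
  ncomp <- 0L
  todo <- which(p & !visited)
  while (length(todo)) {
    ncomp <- ncomp + 1L
    frontier <- todo[1]
    visited[frontier] <- TRUE
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, loff, `+`)))
      frontier <- nb[p[nb] & !visited[nb]]
      visited[frontier] <- TRUE
    }
    todo <- which(p & !visited)
  }
  ncomp
}

# exhaustive patch-overlap detection: returns per-patch truth/pred
# positivity for a flush-ended grid over [lo, hi]
oracle_detection_patches <- function(pred, truth, lo, hi, size = 9L,
                                     overlap = 4L, threshold = 0.10) {
  stride <- size - overlap
  corners <- function(a, b) {
    n <- b - a + 1L
    if (n <= size) return(a)
    cs <- seq.int(a, b - size + 1L, by = stride)
    if (cs[length(cs)] != b - size + 1L) cs <- c(cs, b - size + 1L)
    cs
  }
  d <- dim(truth)
  g <- expand.grid(x = corners(lo[1], hi[1]), y = corners(lo[2], hi[2]),
                   z = corners(lo[3], hi[3]))
  f <- function(mask, cx, cy, cz) {
    tot <- 0L; pos <- 0L
    for (x in cx:min(cx + size - 1L, d[1]))
      for (y in cy:min(cy + size - 1L, d[2]))
        for (z in cz:min(cz + size - 1L, d[3])) {
          tot <- tot + 1L
          if (mask[x, y, z] != 0) pos <- pos + 1L
        }
    pos / tot
  }
  tpos <- ppos <- logical(nrow(g))
  for (i in seq_len(nrow(g))) {
    tpos[i] <- f(truth, g$x[i], g$y[i], g$z[i]) > threshold
    ppos[i] <- f(pred, g$x[i], g$y[i], g$z[i]) > threshold
  }
  list(grid = g, truth_pos = tpos, pred_pos = ppos)
}

# all-bone toy phantom for controlled lesion tests
make_bone_phantom <- function(shape = c(24, 24, 24), spacing = 4) {
  g <- voxel_grid(shape, spacing)
  codes <- tissue_codes()
  phantom_volume(g,
                 ct = array(700, shape),
                 activity = array(1.5, shape),
                 labels = array(codes[["bone"]], shape))
}

# small, fast training setup shared by training tests
tiny_training_setup <- function(n_vol = 2, d = c(16, 16, 16), seed = 11) {
  set.seed(seed)
  inputs <- list(); targets <- list()
  for (i in seq_len(n_vol)) {
    tgt <- array(0L, d)
    ctr <- sample(5:12, 3, replace = TRUE)
    tgt[(ctr[1] - 2):(ctr[1] + 2), (ctr[2] - 2):(ctr[2] + 2),
        (ctr[3] - 2):(ctr[3] + 2)] <- 1L
    x <- array(rnorm(prod(d), sd = 0.3), c(d, 1))
    x[, , , 1] <- x[, , , 1] + tgt * 2
    inputs[[i]] <- x
    targets[[i]] <- tgt
  }
  list(inputs = inputs, targets = targets)
}
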