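#' Dice overlap score
#'
#' `2|A and B| / (|A| + |B|)` as a percentage; defined as 100 when both
#' masks are empty.
#'
#' @param a,b binary masks of identical shape.
#' @return Dice score in percent.
#' @export
dice_score <- function(a, b) {
  if (length(a) != length(b)) stop("masks must have the same shape")
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(100)
  200 * sum(a & b) / denom
}

#' Voxelwise confusion metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and precision
#' `TP/(TP+FP)`, in percent. A metric whose denominator is zero is
#' reported as `NA` rather than 0.
#'
#' @param pred,truth binary masks of identical shape.
#' @return Named numeric vector `sensitivity`, `specificity`,
#'   `precision` (percent), plus the raw `tp`, `fp`, `fn`, `tn` counts as
#'   attribute `counts`.
#' @export
voxel_confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("masks must have the same shape")
  p <- pred != 0; t <- truth != 0
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- c(sensitivity = safe(tp, tp + fn),
           specificity = safe(tn, tn + fp),
           precision = safe(tp, tp + fp))
  attr(out, "counts") <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  out
}

# corner positions of the flush-ended detection grid along one axis
.det_corners <- function(lo, hi, size, stride) {
  n <- hi - lo + 1L
  if (n <= size) return(lo)
  cs <- seq.int(lo, hi - size + 1L, by = stride)
  if (cs[length(cs)] != hi - size + 1L) cs <- c(cs, hi - size + 1L)
  cs
}

#' Lesionwise detection metrics by patch overlap
#'
#' Tiles the evaluation region with 9x9x9 patches overlapping by 4 voxels
#' (stride 5). A patch is positive in a mask when strictly more than 10%
#' of its voxels are lesion. Ground-truth-positive patches detected by
#' the prediction are TPs; sensitivity, specificity and precision are
#' computed over patches. The evaluation region defaults to the bounding
#' box of the truth lesions (the skeleton region, if supplied) expanded
#' by a 9-voxel margin.
#'
#' @param pred,truth binary masks of identical shape.
#' @param region optional logical mask defining the patch universe (e.g.
#'   the skeleton); its bounding box + margin is tiled.
#' @param size,overlap,threshold patch-grid parameters (defaults 9, 4,
#'   0.10).
#' @param margin bounding-box margin in voxels (default 9).
#' @return Named numeric vector (percent) with attribute `counts`
#'   (patch-level tp/fp/fn/tn). Sensitivity is `NA` when the truth has no
#'   positive patch.
#' @export
lesionwise_detection <- function(pred, truth, region = NULL, size = 9L,
                                 overlap = 4L, threshold = 0.10,
                                 margin = 9L) {
  if (!all(dim(pred) == dim(truth))) stop("masks must have the same shape")
  d <- dim(truth)
  base <- if (is.null(region)) truth != 0 else region != 0
  if (!any(base)) base <- array(TRUE, d)
  w <- which(base, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - margin, 1L)
  hi <- pmin(apply(w, 2, max) + margin, d)
  stride <- size - overlap
  cx <- .det_corners(lo[1], hi[1], size, stride)
  cy <- .det_corners(lo[2], hi[2], size, stride)
  cz <- .det_corners(lo[3], hi[3], size, stride)
  g <- expand.grid(x = cx, y = cy, z = cz)
  frac <- function(mask, x, y, z) {
    mean(mask[x:min(x + size - 1L, d[1]),
              y:min(y + size - 1L, d[2]),
              z:min(z + size - 1L, d[3])] != 0)
  }
  tpos <- ppos <- logical(nrow(g))
  for (i in seq_len(nrow(g))) {
    tpos[i] <- frac(truth, g$x[i], g$y[i], g$z[i]) > threshold
    ppos[i] <- frac(pred, g$x[i], g$y[i], g$z[i]) > threshold
  }
  tp <- sum(tpos & ppos); fp <- sum(!tpos & ppos)
  fn <- sum(tpos & !ppos); tn <- sum(!tpos & !ppos)
  safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- c(sensitivity = safe(tp, tp + fn),
           specificity = safe(tn, tn + fp),
           precision = safe(tp, tp + fp))
  attr(out, "counts") <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  out
}

#' Half-maximum lesion segmentation
#'
#' Annotation rule used to delineate one lesion on a PET volume: the
#' local maximum within `radius` voxels of the seed sets the reference,
#' and the mask is the 26-connected component containing the seed among
#' voxels with value >= half that maximum (restricted to the search
#' neighbourhood).
#'
#' @param pet 3D activity array.
#' @param seed voxel index triple (1-based) inside the lesion.
#' @param radius search radius in voxels (default 15).
#' @return Logical mask; empty (with a warning) when the seed value is
#'   below the global mean (background).
#' @export
half_max_segment <- function(pet, seed, radius = 15L) {
  d <- dim(pet)
  seed <- as.integer(seed)
  if (pet[seed[1], seed[2], seed[3]] < mean(pet)) {
    warning("seed lies on background; returning empty mask")
    return(array(FALSE, d))
  }
  lo <- pmax(seed - radius, 1L); hi <- pmin(seed + radius, d)
  sub <- pet[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  thr <- 0.5 * max(sub)
  above <- sub >= thr
  # BFS flood fill (26-connectivity) from the seed within the subvolume
  sd3 <- dim(above)
  start <- seed - lo + 1L
  comp <- array(FALSE, sd3)
  if (!above[start[1], start[2], start[3]]) return(array(FALSE, d))
  idx <- function(p) p[1] + sd3[1] * (p[2] - 1L) + sd3[1] * sd3[2] * (p[3] - 1L)
  queue <- matrix(start, 1)
  comp[start[1], start[2], start[3]] <- TRUE
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (nrow(queue)) {
    p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    nb <- sweep(offs, 2, p, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= sd3[1] & nb[, 2] >= 1 &
      nb[, 2] <= sd3[2] & nb[, 3] >= 1 & nb[, 3] <= sd3[3]
    nb <- nb[ok, , drop = FALSE]
    for (j in seq_len(nrow(nb))) {
      q <- nb[j, ]
      if (above[q[1], q[2], q[3]] && !comp[q[1], q[2], q[3]]) {
        comp[q[1], q[2], q[3]] <- TRUE
        queue <- rbind(queue, q)
      }
    }
  }
  mask <- array(FALSE, d)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- comp
  mask
}

#' Balanced k-fold split
#'
#' Disjoint, exhaustive, size-balanced folds (sizes differ by at most 1),
#' deterministic given the seed.
#'
#' @param ids vector of identifiers.
#' @param k number of folds (default 3).
#' @param seed integer seed.
#' @return List of `k` vectors of ids.
#' @export
kfold_split <- function(ids, k = 3L, seed = 1L) {
  if (k > length(ids)) stop("k exceeds the number of ids")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(ids)
  split(perm, rep_len(seq_len(k), length(ids)))
}

#' Assemble a metric report for one prediction
#'
#' Voxelwise Dice + confusion metrics and lesionwise patch-overlap
#' metrics in one row.
#'
#' @param pred,truth binary masks.
#' @param region optional patch universe for the lesionwise metrics.
#' @param id optional case/fold identifier.
#' @return A one-row data.frame.
#' @export
metric_report <- function(pred, truth, region = NULL, id = NA) {
  vc <- voxel_confusion(pred, truth)
  lw <- lesionwise_detection(pred, truth, region = region)
  data.frame(id = id,
             dice = dice_score(pred, truth),
             sensitivity = vc[["sensitivity"]],
             specificity = vc[["specificity"]],
             precision = vc[["precision"]],
             lesion_sensitivity = lw[["sensitivity"]],
             lesion_specificity = lw[["specificity"]],
             lesion_precision = lw[["precision"]])
}
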