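#' Extract a regular patch grid from volumes
#'
#' Tiles each volume with patches of `size` voxels per axis and `overlap`
#' voxels of overlap (stride `size - overlap`); the final patch per axis
#' is shifted to end flush with the boundary so every voxel is covered.
#' Axes shorter than `size` get a single full-axis patch. The foreground
#' ratio of a reference label volume is recorded per patch.
#'
#' @param labels list of binary 3D label arrays (one per volume), or a
#'   single array.
#' @param size patch edge length (default 64).
#' @param overlap overlap per axis (default 5).
#' @return A data.frame (class `patch_set`): `volume`, `x`, `y`, `z`
#'   (1-based corner), `sx`, `sy`, `sz` (patch size) and `ratio`.
#' @export
extract_patches <- function(labels, size = 64L, overlap = 5L) {
  if (is.array(labels)) labels <- list(labels)
  stride <- size - overlap
  if (stride <= 0) stop("overlap must be smaller than size")
  axis_corners <- function(n) {
    if (n <= size) return(list(corners = 1L, size = as.integer(n)))
    cs <- seq.int(1L, n - size + 1L, by = stride)
    if (cs[length(cs)] != n - size + 1L) cs <- c(cs, n - size + 1L)
    list(corners = as.integer(cs), size = as.integer(size))
  }
  out <- list()
  for (vi in seq_along(labels)) {
    lab <- labels[[vi]]
    d <- dim(lab)
    ax <- lapply(d, axis_corners)
    g <- expand.grid(x = ax[[1]]$corners, y = ax[[2]]$corners,
                     z = ax[[3]]$corners)
    sz <- c(ax[[1]]$size, ax[[2]]$size, ax[[3]]$size)
    ratio <- vapply(seq_len(nrow(g)), function(i) {
      mean(lab[g$x[i]:(g$x[i] + sz[1] - 1L),
               g$y[i]:(g$y[i] + sz[2] - 1L),
               g$z[i]:(g$z[i] + sz[3] - 1L)] == 1)
    }, numeric(1))
    out[[vi]] <- data.frame(volume = vi, x = g$x, y = g$y, z = g$z,
                            sx = sz[1], sy = sz[2], sz = sz[3],
                            ratio = ratio)
  }
  res <- do.call(rbind, out)
  class(res) <- c("patch_set", "data.frame")
  res
}

#' Select the top-k patches by foreground ratio
#'
#' Per volume, keeps the `k` patches with the highest label-to-background
#' ratio (ties broken by lexicographic corner order); if a volume has
#' fewer than `k` patches all are kept. This is the patch-balancing step
#' used for network pretraining.
#'
#' @param ps a `patch_set` from [extract_patches()].
#' @param k patches to keep per volume (default 30).
#' @return A `patch_set` subset.
#' @export
select_top_patches <- function(ps, k = 30L) {
  keep <- unlist(lapply(split(seq_len(nrow(ps)), ps$volume), function(idx) {
    o <- idx[order(-ps$ratio[idx], ps$x[idx], ps$y[idx], ps$z[idx])]
    o[seq_len(min(k, length(o)))]
  }), use.names = FALSE)
  res <- ps[sort(keep), , drop = FALSE]
  class(res) <- c("patch_set", "data.frame")
  res
}

# crop one patch (row i of a patch_set) out of a 3D or 4D array
crop_patch <- function(arr, ps, i) {
  x <- ps$x[i]; y <- ps$y[i]; z <- ps$z[i]
  sx <- ps$sx[i]; sy <- ps$sy[i]; sz <- ps$sz[i]
  if (length(dim(arr)) == 4L)
    arr[x:(x + sx - 1L), y:(y + sy - 1L), z:(z + sz - 1L), , drop = FALSE]
  else
    arr[x:(x + sx - 1L), y:(y + sy - 1L), z:(z + sz - 1L), drop = FALSE]
}
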