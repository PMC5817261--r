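#' Voxel grid geometry
#'
#' A `voxel_grid` records the shape (voxels), spacing (mm per axis) and
#' world origin (mm) of a 3D volume. All fields and label maps of one
#' phantom share a single grid; world coordinates are
#' `origin + index * spacing` with 0-based indices.
#'
#' @param shape integer vector of length 3 (nx, ny, nz), each >= 8.
#' @param spacing numeric vector of length 3, mm per axis, all > 0. A
#'   scalar is recycled (isotropic).
#' @param origin numeric vector of length 3, mm; defaults to zero.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(96, 96, 192), spacing = 4)
#' @export
voxel_grid <- function(shape, spacing = 4, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)))
    stop("shape must be an integer triple")
  if (any(shape < 8L))
    stop("all grid dimensions must be >= 8 voxels")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  if (length(origin) != 3L) stop("origin must be a numeric triple")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing %g x %g x %g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
format.voxel_grid <- function(x, ...) {
  sprintf("%dx%dx%d @ %gx%gx%g mm", x$shape[1], x$shape[2], x$shape[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

grid_equal <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

check_field <- function(field, grid, name = "field") {
  d <- dim(field)
  if (is.null(d) || length(d) != 3L || !all(d == grid$shape))
    stop(sprintf("%s does not match grid shape %s", name,
                 paste(grid$shape, collapse = "x")))
  invisible(TRUE)
}

#' Construct a phantom volume
#'
#' Bundles co-registered CT (Hounsfield units), tracer activity (arbitrary
#' units, nonnegative), and an integer tissue-label map on a shared
#' [voxel_grid], together with the ledger of inserted lesions.
#'
#' Label codes: 0 background/air, 1 soft tissue, 2 lung, 3 liver, 4 spleen,
#' 5 kidney, 6 bone (with marrow), 7 lesion. Lesion labels override bone.
#'
#' @param grid a [voxel_grid].
#' @param ct numeric 3D array, HU.
#' @param activity numeric 3D array, nonnegative.
#' @param labels integer 3D array of tissue codes.
#' @param lesions list of lesion specifications (see [sample_lesions()]).
#' @param meta named list of provenance (seed, marrow background, ...).
#' @return An object of class `phantom_volume`.
#' @export
phantom_volume <- function(grid, ct, activity, labels, lesions = list(),
                           meta = list()) {
  check_field(ct, grid, "ct")
  check_field(activity, grid, "activity")
  check_field(labels, grid, "labels")
  if (any(activity < 0)) stop("activity must be nonnegative everywhere")
  structure(list(grid = grid, ct = ct, activity = activity,
                 labels = labels, lesions = lesions, meta = meta),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat("phantom_volume:", format(x$grid), "\n")
  cat(sprintf("  %d lesion(s); labels present: %s\n", length(x$lesions),
              paste(sort(unique(as.integer(x$labels))), collapse = " ")))
  invisible(x)
}

#' Tissue label codes used by the phantom generator
#' @return Named integer vector of label codes.
#' @export
tissue_codes <- function() {
  c(background = 0L, soft = 1L, lung = 2L, liver = 3L, spleen = 4L,
    kidney = 5L, bone = 6L, lesion = 7L)
}
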