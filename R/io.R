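#' Read a 3D volume from NIfTI-1
#'
#' @param path path to a `.nii`/`.nii.gz` file with a 3D payload.
#' @return A list with `data` (3D array; integer for integer datatypes) and
#'   `grid` (a [voxel_grid] recovered from the header).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D volume in ", path)
  spacing <- attr(img, "pixdim")[seq_len(3)]
  orig <- RNifti::origin(img) # voxel index (1-based) of world origin
  xf <- RNifti::xform(img)
  world0 <- xf[1:3, 4]
  data <- img[, , , drop = TRUE]
  dim(data) <- d
  hdr <- RNifti::niftiHeader(img)
  if (hdr$datatype %in% c(2L, 4L, 8L, 256L, 512L, 768L))
    storage.mode(data) <- "integer"
  list(data = data,
       grid = voxel_grid(d, spacing = spacing, origin = as.numeric(world0)))
}

#' Write a 3D volume as NIfTI-1
#'
#' Integer arrays are stored as 32-bit integers (labels survive a round
#' trip bit-exactly); numeric arrays as 32-bit float.
#'
#' @param field 3D array.
#' @param grid the [voxel_grid] describing it.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(field, grid, path) {
  check_field(field, grid, "field")
  dtype <- if (is.integer(field)) "int32" else "float"
  affine <- diag(c(grid$spacing, 1))
  affine[1:3, 4] <- grid$origin
  attr(field, "pixdim") <- grid$spacing
  img <- RNifti::asNifti(field, datatype = dtype)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load one simulated case and validate shape consistency
#'
#' @param dir directory holding `ct.nii.gz`, `pet.nii.gz`, `labels.nii.gz`.
#' @return list with `ct`, `pet`, `labels`, `grid`.
#' @export
read_case <- function(dir) {
  ct <- read_volume(file.path(dir, "ct.nii.gz"))
  pet <- read_volume(file.path(dir, "pet.nii.gz"))
  lab <- read_volume(file.path(dir, "labels.nii.gz"))
  if (!all(dim(ct$data) == dim(pet$data)) ||
      !all(dim(ct$data) == dim(lab$data)))
    stop("case ", dir, ": ct/pet/labels have mismatched shapes")
  list(ct = ct$data, pet = pet$data, labels = lab$data, grid = ct$grid)
}
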