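#' In-plane parallel-beam projection geometry
#'
#' Builds the sparse system matrix mapping an axial image slice to one
#' sinogram slice: 90 radial bins spanning the image diagonal and 160
#' projection angles uniform over `[0, pi)`. Lines are sampled with
#' bilinear interpolation at a fixed step, so the matrix transpose is the
#' exact adjoint (backprojector).
#'
#' @param grid a [voxel_grid] (in-plane dims and spacing are used).
#' @param nbins radial bins (default 90).
#' @param nang projection angles (default 160).
#' @param step_vox sampling step along each line, in units of the smaller
#'   in-plane voxel size (default 0.5).
#' @return An object of class `pet_geometry` holding the sparse matrix
#'   `A` (`nbins*nang` rows, `nx*ny` columns), bin width (mm) and angles.
#' @export
pet_geometry <- function(grid, nbins = 90L, nang = 160L, step_vox = 0.5) {
  nx <- grid$shape[1]; ny <- grid$shape[2]
  dx <- grid$spacing[1]; dy <- grid$spacing[2]
  tr <- cpp_projector_triplets(nx, ny, dx, dy, as.integer(nbins),
                               as.integer(nang), step_vox * min(dx, dy))
  A <- Matrix::sparseMatrix(i = tr$i + 1L, j = tr$j + 1L, x = tr$x,
                            dims = c(tr$nrow, tr$ncol))
  structure(list(A = A, nbins = as.integer(nbins), nang = as.integer(nang),
                 bin_width = tr$bin_width,
                 angles = pi * (seq_len(nang) - 1L) / nang,
                 grid = grid),
            class = "pet_geometry")
}

#' @export
print.pet_geometry <- function(x, ...) {
  cat(sprintf("pet_geometry: %d bins x %d angles, bin width %.2f mm, image %dx%d\n",
              x$nbins, x$nang, x$bin_width, x$grid$shape[1], x$grid$shape[2]))
  invisible(x)
}

#' PET acquisition model
#'
#' Expected-count budget for one simulated scan: fractions of scattered
#' and uniformly distributed random events, total expected counts, the
#' radial width of the analytic scatter kernel, and the image-domain
#' point-spread FWHM standing in for positron range plus detector blur.
#'
#' @param scatter_fraction proportion of total counts that are scatter.
#' @param randoms_fraction proportion that are randoms.
#' @param total_counts expected total events over the whole sinogram stack.
#' @param scatter_fwhm_mm radial FWHM of the Gaussian scatter kernel.
#' @param psf_fwhm_mm image-domain PSF FWHM applied before projection.
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(scatter_fraction = 0.30,
                              randoms_fraction = 0.30,
                              total_counts = 1e6,
                              scatter_fwhm_mm = 80,
                              psf_fwhm_mm = 4) {
  if (scatter_fraction + randoms_fraction >= 1)
    stop("scatter_fraction + randoms_fraction must be < 1")
  if (total_counts <= 0) stop("total_counts must be positive")
  structure(list(scatter_fraction = scatter_fraction,
                 randoms_fraction = randoms_fraction,
                 total_counts = total_counts,
                 scatter_fwhm_mm = scatter_fwhm_mm,
                 psf_fwhm_mm = psf_fwhm_mm),
            class = "acquisition_model")
}

#' CT number to 511 keV attenuation coefficient
#'
#' Bilinear mapping with its breakpoint at 0 HU: below water the
#' coefficient falls linearly to zero at air (-1000 HU); above water it
#' rises with a shallower bone slope (5.1e-6 per HU per mm), reflecting
#' the reduced photoelectric contribution of bone at annihilation energy.
#' Water is anchored at 0.0096/mm; results are clamped nonnegative.
#'
#' @param ct numeric array or vector of HU values.
#' @return Attenuation coefficients (1/mm), same shape as `ct`.
#' @export
hu_to_mu <- function(ct) {
  if (any(!is.finite(ct))) stop("CT contains non-finite values")
  mu_w <- 0.0096
  mu <- ifelse(ct <= 0, mu_w * (1000 + ct) / 1000, mu_w + ct * 5.1e-6)
  mu[mu < 0] <- 0
  if (!is.null(dim(ct))) dim(mu) <- dim(ct)
  mu
}

.as_slices <- function(field, grid) {
  matrix(field, prod(grid$shape[1:2]), grid$shape[3])
}

.att_sinogram <- function(mu, geom) {
  g <- geom$grid
  check_field(mu, g, "mu")
  exp(-as.matrix(geom$A %*% .as_slices(mu, g)))
}

.sino_array <- function(m, geom) {
  array(m, c(geom$nbins, geom$nang, ncol(m)))
}

#' Attenuated forward projection
#'
#' Per-slice parallel-beam line integrals of the activity, each line
#' attenuated by `exp(-integral of mu)` along the full line of response
#' (exact for PET, where attenuation is independent of the emission
#' point). Linear in activity for fixed `mu`.
#'
#' @param activity 3D activity array on `geom$grid`.
#' @param mu 3D attenuation array (1/mm) on the same grid, or `NULL` for
#'   no attenuation.
#' @param geom a [pet_geometry].
#' @return A `sinogram` object: `data` is an array
#'   `(nbins, nang, n_slices)`, all entries nonnegative.
#' @export
forward_project <- function(activity, mu = NULL, geom) {
  g <- geom$grid
  check_field(activity, g, "activity")
  P <- as.matrix(geom$A %*% .as_slices(activity, g))
  if (!is.null(mu)) P <- P * .att_sinogram(mu, geom)
  sinogram(.sino_array(P, geom), geom)
}

#' Construct a sinogram object
#' @param data array `(nbins, nang, n_slices)`, nonnegative.
#' @param geom the [pet_geometry] it was measured with.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(data, geom) {
  d <- dim(data)
  if (length(d) != 3L || d[1] != geom$nbins || d[2] != geom$nang)
    stop("sinogram data must be (nbins, nang, n_slices)")
  if (any(data < 0)) stop("sinogram entries must be nonnegative")
  structure(list(data = data, geom = geom), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("sinogram: %d bins x %d angles x %d slices, total %.4g counts\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Compose the full measurement expectation
#'
#' Adds scatter and randoms to the true-coincidence expectation and
#' rescales so the components are exact: scatter is the trues sinogram
#' convolved with a wide radial Gaussian and scaled to
#' `scatter_fraction * total_counts`; randoms are spatially uniform with
#' sum `randoms_fraction * total_counts`; the trues are rescaled to the
#' remaining fraction. The output sums to `total_counts` exactly.
#'
#' @param trues a `sinogram` of true coincidences (not all zero).
#' @param model an [acquisition_model].
#' @return List with `expectation` (a `sinogram`), and the `trues`,
#'   `scatter`, `randoms` component arrays.
#' @export
compose_expectation <- function(trues, model = acquisition_model()) {
  x <- trues$data
  tot <- sum(x)
  if (tot <= 0) stop("trues sinogram is all zero; nothing to measure")
  d <- dim(x)
  sf <- model$scatter_fraction; rf <- model$randoms_fraction
  N <- model$total_counts
  sigma_bins <- fwhm_to_sigma(model$scatter_fwhm_mm) / trues$geom$bin_width
  K <- gauss_matrix(d[1], sigma_bins)
  sc <- array(K %*% matrix(x, d[1]), d)
  scatter <- if (sf > 0) sc * (sf * N / sum(sc)) else array(0, d)
  randoms <- array(rf * N / prod(d), d)
  if (rf == 0) randoms <- array(0, d)
  tr <- x * ((1 - sf - rf) * N / tot)
  sinogram_out <- sinogram(tr + scatter + randoms, trues$geom)
  list(expectation = sinogram_out, trues = tr, scatter = scatter,
       randoms = randoms)
}

#' Draw Poisson measurement noise
#'
#' Independent Poisson counts per sinogram bin, deterministic given the
#' seed.
#'
#' @param expectation a `sinogram` of expected counts (>= 0).
#' @param seed integer RNG seed.
#' @return A `sinogram` of integer counts.
#' @export
add_poisson <- function(expectation, seed) {
  x <- expectation$data
  if (any(x < 0)) stop("expectation must be nonnegative")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- array(stats::rpois(length(x), as.numeric(x)), dim(x))
  sinogram(counts, expectation$geom)
}

#' MLEM reconstruction with attenuation correction
#'
#' Standard maximum-likelihood expectation-maximization with the
#' attenuated projector, its exact adjoint, and an optional known additive
#' background (scatter + randoms expectation) inside the forward model.
#' Iterates are nonnegative and the Poisson log-likelihood is
#' non-decreasing. Voxels with zero sensitivity are masked out.
#'
#' @param counts a `sinogram` of measured counts.
#' @param mu attenuation array on the geometry grid (or `NULL`).
#' @param geom a [pet_geometry]; defaults to the sinogram's.
#' @param n_iter number of MLEM iterations (default 20); 0 returns the
#'   initial uniform image.
#' @param background additive expectation array/sinogram (same shape as
#'   counts) or `NULL`.
#' @param psf_fwhm_mm point-spread FWHM modelled inside the forward
#'   projector (resolution recovery); 0 disables it.
#' @return 3D activity estimate on the geometry grid, with attribute
#'   `loglik` (one value per iteration).
#' @export
mlem_reconstruct <- function(counts, mu = NULL, geom = counts$geom,
                             n_iter = 20L, background = NULL,
                             psf_fwhm_mm = 0) {
  g <- geom$grid
  y <- matrix(counts$data, geom$nbins * geom$nang)
  if (any(y < 0)) stop("counts must be nonnegative")
  nz <- ncol(y)
  att <- if (is.null(mu)) matrix(1, nrow(y), nz) else .att_sinogram(mu, geom)
  b <- if (is.null(background)) matrix(0, nrow(y), nz) else {
    bb <- if (inherits(background, "sinogram")) background$data else background
    matrix(bb, nrow(y), nz)
  }
  A <- geom$A
  blur <- psf_fwhm_mm > 0
  sig_vox <- if (blur) fwhm_to_sigma(psf_fwhm_mm) / g$spacing else c(0, 0, 0)
  G <- function(v) { # symmetric kernel, so G is its own adjoint
    if (!blur) return(v)
    matrix(gauss_blur3(array(v, g$shape), sig_vox, sym = TRUE), nrow(v), nz)
  }
  sens <- G(as.matrix(Matrix::crossprod(A, att)))
  ok <- sens > max(sens) * 1e-9
  x <- matrix(0, prod(g$shape[1:2]), nz)
  x[ok] <- mean(y) / mean(sens[ok]) # flat start at a sane scale
  ll <- numeric(0)
  if (n_iter > 0) {
    for (it in seq_len(n_iter)) {
      ybar <- att * as.matrix(A %*% G(x)) + b
      ll <- c(ll, sum(y[ybar > 0] * log(ybar[ybar > 0])) - sum(ybar))
      ratio <- matrix(0, nrow(y), nz)
      pos <- ybar > 0
      ratio[pos] <- y[pos] / ybar[pos]
      bp <- G(as.matrix(Matrix::crossprod(A, att * ratio)))
      x[ok] <- x[ok] * bp[ok] / sens[ok]
    }
  }
  out <- array(x, g$shape)
  attr(out, "loglik") <- ll
  out
}

#' Simulate a full PET study of a phantom
#'
#' Chains the measurement model: CT to attenuation map, image-domain PSF
#' blur of the activity, attenuated forward projection, scatter/randoms
#' composition, Poisson noise, and MLEM reconstruction on the phantom
#' grid.
#'
#' @param phantom a [phantom_volume()].
#' @param model an [acquisition_model].
#' @param seed integer noise seed.
#' @param geom optional precomputed [pet_geometry] (built from the phantom
#'   grid if omitted).
#' @param n_iter MLEM iterations.
#' @return List with `counts` (measured `sinogram`), `expectation`
#'   (composed components), and `recon` (3D array on the phantom grid).
#' @export
simulate_study <- function(phantom, model = acquisition_model(), seed = 1L,
                           geom = NULL, n_iter = 20L) {
  if (is.null(geom)) geom <- pet_geometry(phantom$grid)
  mu <- hu_to_mu(phantom$ct)
  act <- phantom$activity
  if (model$psf_fwhm_mm > 0) {
    act <- gauss_blur3(act, fwhm_to_sigma(model$psf_fwhm_mm) /
                         phantom$grid$spacing)
  }
  trues <- forward_project(act, mu, geom)
  comp <- compose_expectation(trues, model)
  counts <- add_poisson(comp$expectation, seed)
  bg <- comp$scatter + comp$randoms
  recon <- mlem_reconstruct(counts, mu, geom, n_iter = n_iter,
                            background = bg,
                            psf_fwhm_mm = model$psf_fwhm_mm)
  list(counts = counts, expectation = comp, recon = recon)
}
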