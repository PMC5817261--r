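# internal numeric helpers

# dense 1D Gaussian smoothing matrix (rows normalised); sigma in samples
gauss_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-d^2 / (2 * sigma^2))
  K / rowSums(K)
}

# symmetric (unnormalised-edge) smoothing matrix: exactly self-adjoint,
# unit gain in the interior; used where an operator and its adjoint must
# match (PSF modelling inside MLEM)
gauss_matrix_sym <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-d^2 / (2 * sigma^2))
  K / sum(exp(-(seq(-n, n))^2 / (2 * sigma^2)))
}

# separable Gaussian blur of a 3D array; sigma in voxels per axis
gauss_blur3 <- function(arr, sigma, sym = FALSE) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  km <- if (sym) gauss_matrix_sym else gauss_matrix
  d <- dim(arr)
  if (sigma[1] > 0) {
    arr <- array(km(d[1], sigma[1]) %*% matrix(arr, d[1]), d)
  }
  if (sigma[2] > 0) {
    a <- aperm(arr, c(2, 1, 3))
    a <- array(km(d[2], sigma[2]) %*% matrix(a, d[2]), dim(a))
    arr <- aperm(a, c(2, 1, 3))
  }
  if (sigma[3] > 0) {
    a <- aperm(arr, c(3, 2, 1))
    a <- array(km(d[3], sigma[3]) %*% matrix(a, d[3]), dim(a))
    arr <- aperm(a, c(3, 2, 1))
  }
  arr
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# binary dilation by one voxel, 26-connectivity
dilate26 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    out <- out | mask[xs, ys, zs]
  }
  out
}

# deterministic child seeds below 2^31
derive_seed <- function(base, stream, k = 0L) {
  as.integer((as.numeric(base) * 1103 + stream * 7919 + k * 104729) %%
               2147483647)
}
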