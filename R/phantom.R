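#' Default phantom generator configuration
#'
#' Tissue CT means/noise (HU), baseline tracer activity per tissue class
#' (arbitrary units; marrow background is the reference for lesion uptake),
#' and lesion sampling ranges. All values configurable; the defaults aim at
#' the appearance of whole-body CXCR4-tracer PET/CT: lesions are focal
#' skeletal hot spots with 2-10x marrow uptake and a CT change whose
#' magnitude scales with severity.
#'
#' @return Named list of generator parameters.
#' @export
phantom_config <- function() {
  list(
    ct_mean = c(background = -1000, soft = 40, lung = -700, liver = 55,
                spleen = 50, kidney = 45, bone = 700),
    ct_sd   = c(background = 0, soft = 15, lung = 30, liver = 10,
                spleen = 10, kidney = 10, bone = 60),
    activity = c(background = 0, soft = 1.0, lung = 0.2, liver = 2.5,
                 spleen = 2.2, kidney = 3.0, bone = 1.5),
    activity_noise = 0.05,     # multiplicative, smoothed white noise
    marrow_background = 1.5,   # reference activity for lesion uptake
    n_lesions = c(5L, 40L),    # per-phantom count range (uniform)
    semi_axes_mm = c(6, 24),   # ellipsoid semi-axis range
    uptake = c(2, 10),         # x marrow background
    ct_delta = c(-400, 200),   # HU change before severity scaling
    uptake_max = 10,           # severity = uptake / uptake_max
    deform_amp = 0.3,          # radial perturbation, fraction of semi-axis
    min_center_dist_factor = 1.0
  )
}

# normalised coordinate meshes: x,y in [-1,1] across extent, z in [0,1]
norm_coords <- function(grid) {
  s <- grid$shape
  list(x = (seq_len(s[1]) - (s[1] + 1) / 2) / (s[1] / 2),
       y = (seq_len(s[2]) - (s[2] + 1) / 2) / (s[2] / 2),
       z = (seq_len(s[3]) - 0.5) / s[3])
}

# predicate helpers on the normalised mesh, vectorised over the full grid
.mesh <- function(grid) {
  nc <- norm_coords(grid)
  s <- grid$shape
  list(X = array(rep(nc$x, times = s[2] * s[3]), s),
       Y = array(rep(rep(nc$y, each = s[1]), times = s[3]), s),
       Z = array(rep(nc$z, each = s[1] * s[2]), s))
}

#' Build the lesion-free stylized whole-body phantom
#'
#' Constructs a torso-scale anatomy from geometric primitives: an
#' elliptical soft-tissue body, two lungs, liver/spleen/kidneys, and a
#' connected skeleton (femora, pelvic ring, spine with vertebral
#' modulation, rib cage shell, sternum, shoulder girdle, humeri). CT is
#' drawn per tissue class with class-specific noise; activity is the class
#' baseline times mild smooth multiplicative noise.
#'
#' @param grid a [voxel_grid]; every dimension must be at least 16 voxels
#'   so the skeleton template fits.
#' @param seed integer RNG seed; the result is a pure function of
#'   `(grid, seed, config)`.
#' @param config generator parameters, see [phantom_config()].
#' @return A lesion-free [phantom_volume()] with `meta$skeleton_codes`.
#' @export
build_anatomy <- function(grid, seed, config = phantom_config()) {
  if (any(grid$shape < 16L))
    stop("grid too small to contain the skeleton template (need >= 16 voxels per axis)")
  codes <- tissue_codes()
  m <- .mesh(grid)
  X <- m$X; Y <- m$Y; Z <- m$Z
  lab <- array(codes[["background"]], grid$shape)

  body <- (X / 0.55)^2 + (Y / 0.38)^2 <= 1
  lab[body] <- codes[["soft"]]

  lung_l <- ((X + 0.22) / 0.16)^2 + ((Y + 0.05) / 0.18)^2 +
    ((Z - 0.75) / 0.13)^2 <= 1
  lung_r <- ((X - 0.22) / 0.16)^2 + ((Y + 0.05) / 0.18)^2 +
    ((Z - 0.75) / 0.13)^2 <= 1
  lab[(lung_l | lung_r) & body] <- codes[["lung"]]

  liver <- ((X + 0.20) / 0.22)^2 + ((Y + 0.05) / 0.20)^2 +
    ((Z - 0.54) / 0.09)^2 <= 1
  lab[liver & body] <- codes[["liver"]]
  spleen <- ((X - 0.25) / 0.10)^2 + ((Y - 0.05) / 0.10)^2 +
    ((Z - 0.56) / 0.05)^2 <= 1
  lab[spleen & body] <- codes[["spleen"]]
  kid_l <- ((X + 0.16) / 0.07)^2 + ((Y - 0.12) / 0.06)^2 +
    ((Z - 0.45) / 0.05)^2 <= 1
  kid_r <- ((X - 0.16) / 0.07)^2 + ((Y - 0.12) / 0.06)^2 +
    ((Z - 0.45) / 0.05)^2 <= 1
  lab[(kid_l | kid_r) & body] <- codes[["kidney"]]

  # --- skeleton (assigned last so bone overrides organs) ---
  vert <- 1 + 0.15 * sin(2 * pi * Z * 12)          # vertebral modulation
  spine <- (X / (0.08 * vert))^2 + ((Y - 0.22) / (0.08 * vert))^2 <= 1 &
    Z >= 0.26 & Z <= 0.98
  ring_q <- (X / 0.34)^2 + ((Y - 0.02) / 0.26)^2
  pelvis <- ring_q >= 0.55 & ring_q <= 1 & Z >= 0.25 & Z <= 0.36
  shell_q <- (X / 0.42)^2 + ((Y - 0.02) / 0.30)^2
  rib_band <- sin(2 * pi * Z * 10) > 0.1
  ribs <- shell_q >= 0.80 & shell_q <= 1 & rib_band & Z >= 0.60 & Z <= 0.88
  erector <- (X / 0.06)^2 + ((Y - 0.30) / 0.06)^2 <= 1 & Z >= 0.58 & Z <= 0.90
  sternum <- (X / 0.05)^2 + ((Y + 0.28) / 0.05)^2 <= 1 & Z >= 0.62 & Z <= 0.88
  shoulder <- abs(Y - 0.10) <= 0.06 & abs(X) <= 0.45 & Z >= 0.88 & Z <= 0.94
  hum_l <- ((X + 0.40) / 0.06)^2 + ((Y - 0.10) / 0.06)^2 <= 1 &
    Z >= 0.70 & Z <= 0.93
  hum_r <- ((X - 0.40) / 0.06)^2 + ((Y - 0.10) / 0.06)^2 <= 1 &
    Z >= 0.70 & Z <= 0.93
  fem_l <- ((X + 0.26) / 0.07)^2 + ((Y - 0.02) / 0.07)^2 <= 1 &
    Z >= 0.02 & Z <= 0.30
  fem_r <- ((X - 0.26) / 0.07)^2 + ((Y - 0.02) / 0.07)^2 <= 1 &
    Z >= 0.02 & Z <= 0.30
  skel <- (spine | pelvis | ribs | erector | sternum | shoulder |
             hum_l | hum_r | fem_l | fem_r) & body
  lab[skel] <- codes[["bone"]]

  storage.mode(lab) <- "integer"

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ct <- array(0, grid$shape)
  act <- array(0, grid$shape)
  nm <- names(codes)
  for (tn in setdiff(nm, "lesion")) {
    idx <- which(lab == codes[[tn]])
    if (!length(idx)) next
    sdv <- config$ct_sd[[tn]]
    ct[idx] <- config$ct_mean[[tn]] +
      (if (sdv > 0) stats::rnorm(length(idx), 0, sdv) else 0)
    act[idx] <- config$activity[[tn]]
  }
  if (config$activity_noise > 0) {
    noise <- gauss_blur3(array(stats::rnorm(prod(grid$shape)), grid$shape),
                         sigma = 1.5)
    noise <- noise / stats::sd(noise)
    act <- pmax(act * (1 + config$activity_noise * noise), 0)
  }
  phantom_volume(grid, ct, act, lab,
                 meta = list(seed = seed,
                             marrow_background = config$marrow_background,
                             config = config))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Skeleton mask of a phantom (bone plus any lesion voxels)
#' @param phantom a [phantom_volume()].
#' @return logical 3D array.
#' @export
skeleton_mask <- function(phantom) {
  codes <- tissue_codes()
  phantom$labels == codes[["bone"]] | phantom$labels == codes[["lesion"]]
}

# direction-dependent radius factor for a deformed ellipsoid; coefficients
# drawn once per lesion. u: n x 3 matrix of unit directions.
.deform_factor <- function(u, def) {
  if (is.null(def)) return(rep(1, nrow(u)))
  s <- rep(0, nrow(u))
  for (k in seq_len(nrow(def$q))) {
    s <- s + def$w[k] * cos(u %*% def$q[k, ] + def$phi[k])
  }
  1 + def$amp * as.numeric(s)
}

#' Randomly sample bone lesions for a phantom
#'
#' Lesion centres are uniform over skeleton voxels; the per-phantom count
#' is uniform over `n_range`; semi-axes, uptake multiplier and CT change
#' are uniform over the configured ranges. Candidates whose centre falls
#' within the sum of maximal semi-axes of an accepted lesion are redrawn,
#' up to a retry budget of `10 * n` draws; if the budget is exhausted a
#' warning is issued and fewer lesions are returned.
#'
#' @param phantom a [phantom_volume()] with a nonempty skeleton.
#' @param n_range integer interval `c(lo, hi)` for the lesion count.
#' @param seed integer RNG seed.
#' @param config generator parameters, see [phantom_config()].
#' @return List of lesion specs: `id`, `center` (1-based voxel triple),
#'   `semi_axes` (mm), `uptake`, `ct_delta` (HU), `deform`.
#' @export
sample_lesions <- function(phantom, n_range = NULL, seed = 1L,
                           config = phantom_config()) {
  if (is.null(n_range)) n_range <- config$n_lesions
  skel <- which(skeleton_mask(phantom))
  if (!length(skel)) stop("phantom has an empty skeleton")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- if (n_range[1] == n_range[2]) n_range[1] else
    sample(seq.int(n_range[1], n_range[2]), 1L)
  if (n == 0L) return(list())
  sp <- phantom$grid$spacing
  dims <- phantom$grid$shape
  lesions <- list()
  centers_mm <- matrix(0, 0, 3)
  radii_mm <- numeric(0)
  tries <- 0L
  budget <- 10L * n
  while (length(lesions) < n && tries < budget) {
    tries <- tries + 1L
    v <- skel[sample.int(length(skel), 1L)]
    idx <- arrayInd(v, dims)[1, ]
    ctr_mm <- (idx - 1) * sp
    axes <- stats::runif(3, config$semi_axes_mm[1], config$semi_axes_mm[2])
    if (nrow(centers_mm)) {
      d <- sqrt(colSums((t(centers_mm) - ctr_mm)^2))
      if (any(d < config$min_center_dist_factor * (radii_mm + max(axes))))
        next
    }
    def <- if (config$deform_amp > 0) {
      w <- stats::runif(4); w <- w / sum(w)
      list(amp = config$deform_amp, w = w,
           q = matrix(stats::rnorm(12, sd = 2), 4, 3),
           phi = stats::runif(4, 0, 2 * pi))
    } else NULL
    lesions[[length(lesions) + 1L]] <- list(
      id = length(lesions) + 1L,
      center = idx,
      semi_axes = axes,
      uptake = stats::runif(1, config$uptake[1], config$uptake[2]),
      ct_delta = stats::runif(1, config$ct_delta[1], config$ct_delta[2]),
      deform = def)
    centers_mm <- rbind(centers_mm, ctr_mm)
    radii_mm <- c(radii_mm, max(axes))
  }
  if (length(lesions) < n)
    warning(sprintf("lesion retry budget exhausted: placed %d of %d",
                    length(lesions), n))
  lesions
}

# voxel mask of one lesion; returns linear indices into the grid
lesion_mask_indices <- function(lesion, grid) {
  sp <- grid$spacing; dims <- grid$shape
  amp <- if (is.null(lesion$deform)) 0 else lesion$deform$amp
  half_vox <- ceiling(lesion$semi_axes * (1 + amp) / sp) + 1L
  lo <- pmax(lesion$center - half_vox, 1L)
  hi <- pmin(lesion$center + half_vox, dims)
  if (any(lo > hi)) return(integer(0))
  xs <- seq.int(lo[1], hi[1]); ys <- seq.int(lo[2], hi[2])
  zs <- seq.int(lo[3], hi[3])
  g <- expand.grid(x = xs, y = ys, z = zs)
  p <- sweep(as.matrix(g), 2, lesion$center) # voxel offsets
  p <- sweep(p, 2, sp, `*`)                  # mm
  r <- sweep(p, 2, lesion$semi_axes, `/`)
  rn <- sqrt(rowSums(r^2))
  inside <- rn <= 1e-9
  nz <- which(rn > 1e-9)
  if (length(nz)) {
    u <- r[nz, , drop = FALSE] / rn[nz]
    f <- .deform_factor(u, lesion$deform)
    inside[nz] <- rn[nz] <= f
  }
  sel <- g[inside, , drop = FALSE]
  if (!nrow(sel)) return(integer(0))
  sel$x + dims[1] * (sel$y - 1L) + dims[1] * dims[2] * (sel$z - 1L)
}

#' Insert lesions into a phantom
#'
#' For each lesion, voxels inside its (deformed) ellipsoid are relabelled
#' as lesion, their activity is multiplied by the uptake factor, and their
#' CT value is shifted by `ct_delta * severity` where severity =
#' `uptake / uptake_max` (more avid disease destroys or remodels more
#' bone). Lesions falling partly outside the grid are clipped with a
#' warning; re-applying a lesion id already present is a no-op.
#'
#' @param phantom a [phantom_volume()].
#' @param lesions list from [sample_lesions()].
#' @param config generator parameters (for `uptake_max`).
#' @return A new [phantom_volume()] with lesions applied and recorded.
#' @export
apply_lesions <- function(phantom, lesions, config = phantom_config()) {
  if (!length(lesions)) return(phantom)
  codes <- tissue_codes()
  done <- vapply(phantom$lesions, `[[`, integer(1), "id")
  dims <- phantom$grid$shape
  # lesions live in (or immediately adjacent to) the skeleton
  skel_ok <- dilate26(skeleton_mask(phantom))
  for (les in lesions) {
    if (les$id %in% done) next
    amp <- if (is.null(les$deform)) 0 else les$deform$amp
    half_vox <- ceiling(les$semi_axes * (1 + amp) / phantom$grid$spacing)
    if (any(les$center - half_vox < 1L) || any(les$center + half_vox > dims))
      warning(sprintf("lesion %d extends outside the grid; clipped", les$id))
    idx <- lesion_mask_indices(les, phantom$grid)
    idx <- idx[skel_ok[idx]]
    if (!length(idx)) next
    severity <- les$uptake / config$uptake_max
    # voxels already claimed by an overlapping lesion keep their values:
    # uptake factors do not compound
    fresh <- idx[phantom$labels[idx] != codes[["lesion"]]]
    phantom$labels[idx] <- codes[["lesion"]]
    phantom$activity[fresh] <- phantom$activity[fresh] * les$uptake
    phantom$ct[fresh] <- phantom$ct[fresh] + les$ct_delta * severity
    phantom$lesions[[length(phantom$lesions) + 1L]] <- les
    done <- c(done, les$id)
  }
  phantom
}

#' Generate a full synthetic phantom (anatomy + random lesions)
#'
#' Convenience wrapper: [build_anatomy()], [sample_lesions()],
#' [apply_lesions()] with seeds derived from one master seed.
#'
#' @inheritParams build_anatomy
#' @param n_range lesion-count interval; defaults from `config`.
#' @return A [phantom_volume()] with lesions.
#' @export
generate_phantom <- function(grid, seed, n_range = NULL,
                             config = phantom_config()) {
  ph <- build_anatomy(grid, seed = derive_seed(seed, 1L), config = config)
  les <- sample_lesions(ph, n_range = n_range,
                        seed = derive_seed(seed, 2L), config = config)
  apply_lesions(ph, les, config = config)
}
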