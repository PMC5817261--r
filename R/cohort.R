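#' Default run configuration
#'
#' Nested configuration covering the phantom grid, generator parameters,
#' acquisition model, reconstruction, network/training and baseline
#' settings, plus all seeds. Serialisable to/from YAML; unknown keys in a
#' user file are rejected.
#'
#' @return Nested named list (class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    grid = list(shape = c(96L, 96L, 192L), spacing = c(4, 4, 4)),
    phantom = phantom_config(),
    acquisition = list(scatter_fraction = 0.30, randoms_fraction = 0.30,
                       total_counts = 1e6, scatter_fwhm_mm = 80,
                       psf_fwhm_mm = 4),
    recon = list(n_iter = 20L, step_vox = 0.5),
    network = list(depth = 3L, base_width = 16L, width_cap = 128L),
    training = list(lr = 0.001, momentum = 0.95, pretrain_iters = 1000L,
                    eval_every = 100L, patience = 5L, min_delta = 1e-4,
                    max_finetune_iters = 1000L, batch_size = 2L,
                    patch_size = 64L, overlap = 5L, top_k = 30L),
    baseline = list(n_trees = 20L, k_neighbors = 15L, svm_cost = 0.5,
                    samples_per_class = 2000L, pca_dim = 15L, cv_folds = 3L),
    cohort = list(n = 70L),
    seeds = list(phantom = 1L, noise = 2L, training = 3L, sampling = 4L)
  ), class = "run_config")
}

# recursive merge that rejects keys absent from the defaults
.merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    if (!k %in% names(base))
      stop("unknown configuration key: ", paste0(path, k))
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- .merge_config(base[[k]], override[[k]],
                                 paste0(path, k, "."))
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read a YAML run configuration
#' @param path YAML file; keys not present in [default_config()] raise an
#'   error.
#' @return A `run_config` list merged over the defaults.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- .merge_config(unclass(default_config()), user)
  structure(cfg, class = "run_config")
}

.cfg_grid <- function(config) {
  voxel_grid(config$grid$shape, spacing = config$grid$spacing)
}
.cfg_model <- function(config) {
  do.call(acquisition_model, config$acquisition)
}

#' Generate a cohort of simulated phantom studies
#'
#' Writes `n` phantoms (distinct derived seeds), each with CT, true
#' activity, ground-truth labels, the measured sinogram stack and the
#' MLEM reconstruction, plus a machine-readable JSON manifest. On I/O
#' failure the partially written cohort is removed.
#'
#' @param out_dir output directory (created; must not already contain a
#'   manifest).
#' @param n number of phantoms (default from config: 70).
#' @param base_seed master seed; per-phantom seeds derive from it.
#' @param config a `run_config` (see [default_config()]).
#' @param simulate also run the PET measurement simulation (default TRUE).
#' @return The manifest, invisibly (list with one entry per phantom).
#' @export
generate_cohort <- function(out_dir, n = NULL, base_seed = 1L,
                            config = default_config(), simulate = TRUE) {
  if (is.null(n)) n <- config$cohort$n
  if (n < 1) stop("n must be >= 1")
  grid <- .cfg_grid(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path))
    stop("output directory already holds a cohort manifest: ", out_dir)
  geom <- if (simulate) pet_geometry(grid, step_vox = config$recon$step_vox)
          else NULL
  model <- .cfg_model(config)
  entries <- vector("list", n)
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(out_dir, c("manifest.json",
                                               sprintf("phantom_%03d", seq_len(n)))),
                          recursive = TRUE), add = TRUE)
  for (i in seq_len(n)) {
    pseed <- derive_seed(base_seed, 100L, i)
    nseed <- derive_seed(base_seed, 200L, i)
    ph <- generate_phantom(grid, seed = pseed, config = config$phantom)
    case_dir <- file.path(out_dir, sprintf("phantom_%03d", i))
    dir.create(case_dir, showWarnings = FALSE)
    write_volume(ph$ct, grid, file.path(case_dir, "ct.nii.gz"))
    write_volume(ph$activity, grid, file.path(case_dir, "activity.nii.gz"))
    write_volume(ph$labels, grid, file.path(case_dir, "labels.nii.gz"))
    files <- c("ct.nii.gz", "activity.nii.gz", "labels.nii.gz")
    if (simulate) {
      st <- simulate_study(ph, model, seed = nseed, geom = geom,
                           n_iter = config$recon$n_iter)
      write_volume(st$recon, grid, file.path(case_dir, "pet.nii.gz"))
      cg <- voxel_grid(dim(st$counts$data), spacing = c(geom$bin_width, 1, 1))
      write_volume(st$counts$data * 1.0, cg,
                   file.path(case_dir, "sinogram.nii.gz"))
      jsonlite::write_json(list(nbins = geom$nbins, nang = geom$nang,
                                bin_width_mm = geom$bin_width,
                                total_counts = sum(st$counts$data),
                                scatter_fraction = model$scatter_fraction,
                                randoms_fraction = model$randoms_fraction,
                                noise_seed = nseed),
                           file.path(case_dir, "sinogram.json"),
                           auto_unbox = TRUE)
      files <- c(files, "pet.nii.gz", "sinogram.nii.gz", "sinogram.json")
    }
    entries[[i]] <- list(id = i, dir = basename(case_dir), files = files,
                         phantom_seed = pseed, noise_seed = nseed,
                         n_lesions = length(ph$lesions))
  }
  manifest <- list(n = n, base_seed = base_seed,
                   grid = list(shape = grid$shape, spacing = grid$spacing),
                   simulated = simulate, entries = entries)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}
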