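#' Configuration of the scaled-down phantom segmentation study
#'
#' The desk-scale replication of the phantom experiment: a torso-section
#' grid at 3 mm spacing chosen so lesions subtend the same voxel counts
#' as in a clinical-matrix study, a reduced per-phantom lesion count for
#' the smaller field of view, a narrow V-Net, and a shortened two-phase
#' training schedule. See the methods vignette for the scaling rationale.
#'
#' @param n cohort size (default 12).
#' @param holdout phantoms held out for testing (default 3).
#' @return Named list with `grid`, `phantom` (generator config), `n`,
#'   `holdout`, `base_width`, `schedule`, and `mlem_iter`.
#' @export
phantom_study_defaults <- function(n = 12L, holdout = 3L) {
  cfg <- phantom_config()
  cfg$n_lesions <- c(5L, 15L)
  list(grid = voxel_grid(c(64L, 64L, 96L), spacing = 3),
       phantom = cfg,
       n = as.integer(n), holdout = as.integer(holdout),
       base_width = 8L,
       schedule = training_schedule(pretrain_iters = 1000L,
                                    max_finetune_iters = 1000L,
                                    patch_size = 16L, batch_size = 4L),
       mlem_iter = 20L)
}

#' Simulate a cohort in memory
#'
#' Convenience for experiments: generates `n` phantoms and their PET
#' studies without touching disk.
#'
#' @param n number of phantoms.
#' @param grid a [voxel_grid].
#' @param base_seed master seed.
#' @param config phantom generator parameters ([phantom_config()]).
#' @param model an [acquisition_model].
#' @param n_iter MLEM iterations.
#' @param geom optional shared [pet_geometry].
#' @return List of cases, each with `ct`, `pet` (reconstruction),
#'   `labels`, `lesion` and `bone` masks, and the lesion ledger.
#' @export
simulate_cases <- function(n, grid, base_seed = 1L,
                           config = phantom_config(),
                           model = acquisition_model(), n_iter = 20L,
                           geom = NULL) {
  if (is.null(geom)) geom <- pet_geometry(grid)
  codes <- tissue_codes()
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(grid, seed = derive_seed(base_seed, 100L, i),
                           config = config)
    st <- simulate_study(ph, model, seed = derive_seed(base_seed, 200L, i),
                         geom = geom, n_iter = n_iter)
    list(ct = ph$ct, pet = st$recon,
         labels = ph$labels,
         lesion = ph$labels == codes[["lesion"]],
         bone = ph$labels == codes[["bone"]] |
           ph$labels == codes[["lesion"]],
         lesions = ph$lesions)
  })
}

#' Stack normalised input channels for a case
#'
#' @param case one element of [simulate_cases()] output.
#' @param channels subset of `c("ct", "pet")`.
#' @return 4D array `(nx, ny, nz, length(channels))`, each channel
#'   z-scored.
#' @export
case_channels <- function(case, channels = c("ct", "pet")) {
  stopifnot(all(channels %in% c("ct", "pet")))
  d <- dim(case$ct)
  x <- array(0, c(d, length(channels)))
  for (i in seq_along(channels))
    x[, , , i] <- normalize_volume(case[[channels[i]]])
  x
}

# pooled metrics over a list of (pred, truth) pairs: counts are summed
# across volumes before forming the ratios
pooled_metrics <- function(preds, truths) {
  cnt <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_along(preds)) {
    vc <- voxel_confusion(preds[[i]], truths[[i]])
    cnt <- cnt + attr(vc, "counts")
  }
  dice <- 200 * cnt[["tp"]] / (2 * cnt[["tp"]] + cnt[["fp"]] + cnt[["fn"]])
  c(dice = dice,
    sensitivity = 100 * cnt[["tp"]] / (cnt[["tp"]] + cnt[["fn"]]),
    specificity = 100 * cnt[["tn"]] / (cnt[["tn"]] + cnt[["fp"]]),
    precision = if (cnt[["tp"]] + cnt[["fp"]] == 0) NA_real_ else
      100 * cnt[["tp"]] / (cnt[["tp"]] + cnt[["fp"]]))
}

#' Run a scaled-down phantom segmentation study
#'
#' Trains a V-Net (or W-Net) on the first `n - holdout` simulated cases
#' and evaluates on the held-out remainder: pooled voxelwise metrics over
#' the test volumes, per-volume metric rows, and the lesionwise
#' patch-overlap metrics.
#'
#' @param cases list from [simulate_cases()].
#' @param holdout number of final cases reserved for testing.
#' @param channels input channels for a V-Net (`"ct"`, `"pet"` or both);
#'   ignored for the W-Net.
#' @param arch `"vnet"` or `"wnet"`.
#' @param base_width finest-stage feature width.
#' @param schedule a [training_schedule()].
#' @param seed integer seed (weights + batch sampling).
#' @param calibrate_threshold pick the decision threshold that maximises
#'   pooled Dice on the training volumes (the weighted loss shifts the
#'   0.5 operating point towards recall; calibration restores a
#'   Dice-optimal one without touching the test data; at most the first
#'   three training volumes are used). `FALSE` keeps the fixed 0.5
#'   threshold.
#' @param stage1_schedule optional separate schedule for the W-Net
#'   skeleton stage.
#' @return List with `model`, `pooled` (named vector), `per_volume`
#'   (data.frame), `lesionwise` (named vector, pooled patch counts) and
#'   `threshold`.
#' @export
run_phantom_study <- function(cases, holdout = 3L,
                              channels = c("ct", "pet"),
                              arch = c("vnet", "wnet"),
                              base_width = 8L,
                              schedule = training_schedule(),
                              seed = 1L, calibrate_threshold = TRUE,
                              stage1_schedule = NULL) {
  arch <- match.arg(arch)
  n <- length(cases)
  stopifnot(holdout >= 1L, holdout < n)
  tr <- seq_len(n - holdout)
  te <- seq.int(n - holdout + 1L, n)
  targets <- lapply(cases, function(cs) cs$lesion * 1L)

  if (arch == "vnet") {
    spec <- vnet_spec(depth = 3L, in_channels = length(channels),
                      base_width = base_width)
    model <- build_vnet(spec, seed = derive_seed(seed, 31L))
    inputs <- lapply(cases, case_channels, channels = channels)
    model <- train_vnet(model, inputs[tr], targets[tr], schedule,
                        seed = derive_seed(seed, 32L))
    prob_of <- function(i)
      predict_volume(model, inputs[[i]],
                     patch_size = schedule$patch_size,
                     overlap = schedule$overlap)$prob
  } else {
    model <- build_wnet(vnet_spec(5L, 1L, base_width = base_width),
                        vnet_spec(3L, 3L, base_width = base_width),
                        seed = derive_seed(seed, 31L))
    ctn <- lapply(cases, function(cs) normalize_volume(cs$ct))
    petn <- lapply(cases, function(cs) normalize_volume(cs$pet))
    bone <- lapply(cases, function(cs) cs$bone * 1L)
    model <- train_wnet(model, ctn[tr], petn[tr], bone[tr], targets[tr],
                        schedule, seed = derive_seed(seed, 32L),
                        stage1_schedule =
                          if (is.null(stage1_schedule)) schedule
                          else stage1_schedule)
    prob_of <- function(i)
      predict_volume(model, list(ct = ctn[[i]], pet = petn[[i]]),
                     patch_size = schedule$patch_size,
                     overlap = schedule$overlap)$prob
  }
  threshold <- 0.5
  if (calibrate_threshold) {
    grid_thr <- c(0.5, 0.6, 0.7, 0.8, 0.85, 0.88, 0.9, 0.92, 0.94,
                  0.96, 0.97)
    cnt <- matrix(0, length(grid_thr), 3,
                  dimnames = list(NULL, c("tp", "fp", "fn")))
    for (i in tr[seq_len(min(3L, length(tr)))]) {
      pp <- prob_of(i)
      tt <- cases[[i]]$lesion
      for (k in seq_along(grid_thr)) {
        pm <- pp > grid_thr[k]
        cnt[k, ] <- cnt[k, ] + c(sum(pm & tt), sum(pm & !tt), sum(!pm & tt))
      }
    }
    dice_tr <- 2 * cnt[, "tp"] / (2 * cnt[, "tp"] + cnt[, "fp"] + cnt[, "fn"])
    threshold <- grid_thr[which.max(dice_tr)]
  }
  preds <- lapply(te, function(i) prob_of(i) > threshold)
  truths <- lapply(te, function(i) cases[[i]]$lesion)
  per_volume <- do.call(rbind, lapply(seq_along(te), function(j)
    metric_report(preds[[j]], truths[[j]],
                  region = cases[[te[j]]]$bone, id = te[j])))
  lw_cnt <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (j in seq_along(te)) {
    lw <- lesionwise_detection(preds[[j]], truths[[j]],
                               region = cases[[te[j]]]$bone)
    lw_cnt <- lw_cnt + attr(lw, "counts")
  }
  safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  lesionwise <- c(sensitivity = safe(lw_cnt[["tp"]],
                                     lw_cnt[["tp"]] + lw_cnt[["fn"]]),
                  specificity = safe(lw_cnt[["tn"]],
                                     lw_cnt[["tn"]] + lw_cnt[["fp"]]),
                  precision = safe(lw_cnt[["tp"]],
                                   lw_cnt[["tp"]] + lw_cnt[["fp"]]))
  list(model = model, pooled = pooled_metrics(preds, truths),
       per_volume = per_volume, lesionwise = lesionwise,
       test_ids = te, preds = preds, threshold = threshold)
}
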