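#' Baseline classifier configuration
#'
#' Fixed hyperparameters for the classical voxel classifiers: 20 random
#' forest trees, 15 nearest neighbours, linear SVM with C = 0.5, 2000
#' lesion + 2000 nonlesion training samples per volume, PCA to 15
#' components, and 3 folds for the optional grid search.
#'
#' @param n_trees,k_neighbors,svm_cost,samples_per_class,pca_dim,cv_folds
#'   see description.
#' @return Named list (class `baseline_config`).
#' @export
baseline_config <- function(n_trees = 20L, k_neighbors = 15L,
                            svm_cost = 0.5, samples_per_class = 2000L,
                            pca_dim = 15L, cv_folds = 3L) {
  stopifnot(n_trees > 0, k_neighbors > 0, svm_cost > 0,
            samples_per_class > 0, pca_dim > 0, cv_folds > 0)
  structure(as.list(environment()), class = "baseline_config")
}

#' Patchwise intensity features
#'
#' The 3x3x3 neighbourhood intensities of the CT volume (27 values, raster
#' order x fastest) concatenated with the PET neighbourhood (27 values):
#' a 54-dimensional feature vector per voxel. Boundaries use
#' edge-replicated padding. Volumes should be z-score normalised first
#' (see [normalize_volume()]); `normalize = TRUE` does this here.
#'
#' @param ct,pet 3D arrays of identical shape.
#' @param voxels integer matrix `n x 3` of 1-based voxel indices.
#' @param normalize z-score each volume before extraction (default TRUE).
#' @return Numeric matrix `n x 54`.
#' @export
patch_features <- function(ct, pet, voxels, normalize = TRUE) {
  if (!all(dim(ct) == dim(pet))) stop("ct and pet must share a grid")
  if (is.null(dim(voxels))) voxels <- matrix(voxels, nrow = 1)
  d <- dim(ct)
  if (normalize) { ct <- normalize_volume(ct); pet <- normalize_volume(pet) }
  n <- nrow(voxels)
  out <- matrix(0, n, 54)
  col <- 0L
  for (vol in list(ct, pet)) {
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      col <- col + 1L
      xs <- pmin(pmax(voxels[, 1] + dx, 1L), d[1])
      ys <- pmin(pmax(voxels[, 2] + dy, 1L), d[2])
      zs <- pmin(pmax(voxels[, 3] + dz, 1L), d[3])
      out[, col] <- vol[cbind(xs, ys, zs)]
    }
  }
  out
}

#' Sample a balanced voxel training set
#'
#' Per volume, draws `samples_per_class` lesion-voxel and nonlesion-voxel
#' centres uniformly without replacement (with replacement, with a
#' warning, when a class has fewer voxels) and extracts their
#' [patch_features()]. Volumes without lesion voxels are skipped with a
#' warning.
#'
#' @param volumes list of cases, each a list with `ct`, `pet`, `labels`
#'   (binary lesion labels or the phantom label map).
#' @param seed integer seed.
#' @param config a [baseline_config()].
#' @return List with `features` (matrix n x 54) and `targets` (factor
#'   "lesion"/"nonlesion").
#' @export
sample_training_set <- function(volumes, seed = 1L,
                                config = baseline_config()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  codes <- tissue_codes()
  feats <- list(); targs <- list()
  m <- config$samples_per_class
  for (vi in seq_along(volumes)) {
    v <- volumes[[vi]]
    lesion <- if (max(v$labels) > 1) v$labels == codes[["lesion"]]
              else v$labels != 0
    pos <- which(lesion); neg <- which(!lesion)
    if (!length(pos)) {
      warning(sprintf("volume %d has no lesion voxels; skipped", vi))
      next
    }
    draw <- function(idx) {
      if (length(idx) >= m) sample(idx, m)
      else {
        warning(sprintf("volume %d: sampling with replacement (%d < %d)",
                        vi, length(idx), m))
        sample(idx, m, replace = TRUE)
      }
    }
    sel <- c(draw(pos), draw(neg))
    vox <- arrayInd(sel, dim(v$ct))
    feats[[length(feats) + 1L]] <- patch_features(v$ct, v$pet, vox)
    targs[[length(targs) + 1L]] <- rep(c("lesion", "nonlesion"), each = m)
  }
  if (!length(feats)) stop("no volume contributed training samples")
  list(features = do.call(rbind, feats),
       targets = factor(unlist(targs), levels = c("nonlesion", "lesion")))
}

#' Fit a classical voxel classifier
#'
#' PCA (fitted on the training features) reduces the 54 intensities to 15
#' components; the chosen classifier is then fitted on the reduced
#' features with the reference hyperparameters, or with a small 3-fold
#' grid search around them when `grid_search = TRUE`.
#'
#' @param features matrix `n x 54`.
#' @param targets factor with levels nonlesion/lesion.
#' @param method one of `"rf"`, `"knn"`, `"svm"`.
#' @param config a [baseline_config()].
#' @param seed integer seed.
#' @param grid_search tune the main hyperparameter by cross-validation?
#' @return Object of class `baseline_model`.
#' @export
fit_baseline <- function(features, targets, method = c("rf", "knn", "svm"),
                         config = baseline_config(), seed = 1L,
                         grid_search = FALSE) {
  method <- match.arg(method)
  if (nlevels(droplevels(targets)) < 2)
    stop("both classes must be present")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pca <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  if (sum(pca$sdev > 1e-12) < config$pca_dim)
    warning("feature matrix is rank deficient below the PCA dimension")
  ndim <- min(config$pca_dim, ncol(pca$rotation))
  red <- pca$x[, seq_len(ndim), drop = FALSE]

  hyper <- switch(method, rf = config$n_trees, knn = config$k_neighbors,
                  svm = config$svm_cost)
  if (grid_search) {
    grid <- switch(method,
                   rf = unique(pmax(1L, round(config$n_trees * c(.5, 1, 2)))),
                   knn = unique(pmax(1L, round(config$k_neighbors *
                                                 c(1 / 3, 1, 2)))),
                   svm = config$svm_cost * c(0.2, 1, 5))
    folds <- kfold_split(seq_len(nrow(red)), k = config$cv_folds,
                         seed = seed)
    acc <- vapply(grid, function(hv) {
      mean(vapply(folds, function(te) {
        tr <- setdiff(seq_len(nrow(red)), te)
        fitted <- .fit_one(red[tr, , drop = FALSE], targets[tr], method, hv)
        mean(.predict_one(fitted, red[te, , drop = FALSE], method,
                          red[tr, , drop = FALSE], targets[tr], hv) ==
               targets[te])
      }, numeric(1)))
    }, numeric(1))
    hyper <- grid[which.max(acc)]
  }
  fit <- .fit_one(red, targets, method, hyper)
  structure(list(method = method, fit = fit, pca = pca, ndim = ndim,
                 hyper = hyper, config = config,
                 train_x = red, train_y = targets),
            class = "baseline_model")
}

.fit_one <- function(x, y, method, hyper) {
  switch(method,
         rf = randomForest::randomForest(x, y, ntree = hyper),
         knn = NULL, # k-NN is lazy: the training set itself is the model
         svm = e1071::svm(x, y, kernel = "linear", cost = hyper,
                          scale = FALSE))
}

.predict_one <- function(fit, newx, method, train_x, train_y, hyper) {
  switch(method,
         rf = stats::predict(fit, newx),
         knn = class::knn(train_x, newx, train_y, k = hyper),
         svm = stats::predict(fit, newx))
}

#' Predict a lesion mask with a fitted baseline
#'
#' Classifies every voxel (optionally restricted to a region mask, e.g.
#' the skeleton) via its patchwise features projected through the
#' training PCA.
#'
#' @param model a `baseline_model`.
#' @param ct,pet 3D arrays.
#' @param region optional logical mask; voxels outside stay negative.
#' @param chunk voxels per prediction block (default 50000).
#' @return Logical lesion mask of the input shape.
#' @export
predict_baseline <- function(model, ct, pet, region = NULL,
                             chunk = 50000L) {
  d <- dim(ct)
  vox_idx <- if (is.null(region)) seq_len(prod(d)) else which(region != 0)
  mask <- array(FALSE, d)
  ctn <- normalize_volume(ct); petn <- normalize_volume(pet)
  for (start in seq(1L, length(vox_idx), by = chunk)) {
    sel <- vox_idx[start:min(start + chunk - 1L, length(vox_idx))]
    f <- patch_features(ctn, petn, arrayInd(sel, d), normalize = FALSE)
    red <- scale(f, center = model$pca$center, scale = FALSE) %*%
      model$pca$rotation[, seq_len(model$ndim), drop = FALSE]
    pr <- .predict_one(model$fit, red, model$method, model$train_x,
                       model$train_y, model$hyper)
    mask[sel] <- pr == "lesion"
  }
  mask
}
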