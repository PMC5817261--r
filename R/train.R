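#' Training schedule
#'
#' Two-phase schedule: pretraining on the class-balanced top-k patches,
#' then fine-tuning on the full extracted patch grid until the running
#' loss stops improving. SGD runs every iteration; checkpoints (loss
#' bookkeeping and the convergence test) happen every `eval_every`
#' iterations.
#'
#' @param lr learning rate (default 0.001).
#' @param momentum SGD momentum (default 0.95).
#' @param pretrain_iters phase-1 iterations (default 1000).
#' @param eval_every checkpoint interval in iterations (default 100).
#' @param patience checkpoints without improvement before phase 2 stops
#'   (default 5).
#' @param min_delta minimum loss improvement that counts (default 1e-4).
#' @param max_finetune_iters hard cap on phase-2 iterations (default 1000).
#' @param batch_size patches per SGD step (default 2).
#' @param patch_size training patch edge length (default 64).
#' @param overlap patch overlap in voxels (default 5).
#' @param top_k balanced patches kept per volume for pretraining
#'   (default 30).
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(lr = 0.001, momentum = 0.95,
                              pretrain_iters = 1000L, eval_every = 100L,
                              patience = 5L, min_delta = 1e-4,
                              max_finetune_iters = 1000L, batch_size = 2L,
                              patch_size = 64L, overlap = 5L, top_k = 30L) {
  if (lr <= 0) stop("learning rate must be positive")
  if (patience < 1L) stop("patience must be >= 1")
  structure(as.list(environment()), class = "training_schedule")
}

# in-place-style SGD with momentum; returns list(model, velocity)
.sgd_step <- function(params, vel, grads, lr, momentum) {
  walk <- function(p, v, g) {
    if (!is.null(p$W)) {
      if (is.null(v)) v <- list(W = 0 * p$W, b = 0 * p$b)
      v$W <- momentum * v$W - lr * g$dW
      v$b <- momentum * v$b - lr * g$db
      p$W <- p$W + v$W
      p$b <- p$b + v$b
      return(list(p = p, v = v))
    }
    vv <- if (is.null(v)) vector("list", length(p)) else v
    keys <- if (!is.null(names(p))) names(p) else seq_along(p)
    for (i in keys) {
      r <- walk(p[[i]], vv[[i]], g[[i]])
      p[[i]] <- r$p; vv[[i]] <- r$v
    }
    list(p = p, v = vv)
  }
  walk(params, vel, grads)
}

# accumulate two gradient trees
.grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (!is.null(a$dW)) return(list(dW = a$dW + b$dW, db = a$db + b$db))
  for (i in seq_along(a)) a[[i]] <- .grad_add(a[[i]], b[[i]])
  a
}
.grad_scale <- function(a, s) {
  if (!is.null(a$dW)) return(list(dW = a$dW * s, db = a$db * s))
  for (i in seq_along(a)) a[[i]] <- .grad_scale(a[[i]], s)
  a
}

#' Per-volume z-score normalisation
#' @param v numeric array.
#' @return Array with zero mean and unit variance (constant arrays map
#'   to zero).
#' @export
normalize_volume <- function(v) {
  s <- stats::sd(v)
  if (s == 0) return(v * 0)
  (v - mean(v)) / s
}

# one SGD pass over `iters` iterations sampling rows of `pool`
.run_phase <- function(model, vel, inputs, targets, pool, weights, sched,
                       iters, phase, history, check_converge = FALSE) {
  if (iters <= 0L || nrow(pool) == 0L) return(list(model = model, vel = vel,
                                                   history = history))
  win <- c()
  best <- Inf
  stale <- 0L
  for (it in seq_len(iters)) {
    rows <- sample.int(nrow(pool), min(sched$batch_size, nrow(pool)),
                       replace = nrow(pool) < sched$batch_size)
    gacc <- NULL
    lsum <- 0
    for (r in rows) {
      vi <- pool$volume[r]
      xin <- crop_patch(inputs[[vi]], pool, r)
      tgt <- crop_patch(targets[[vi]], pool, r)
      fw <- vnet_forward(model, xin, cache = TRUE)
      lsum <- lsum + wce_from_logits(fw$logits, tgt, weights)
      dl <- wce_logit_grad(fw$logits, tgt, weights)
      g <- vnet_backward(model, fw$cache, dl)
      gacc <- .grad_add(gacc, g)
    }
    gacc <- .grad_scale(gacc, 1 / length(rows))
    loss <- lsum / length(rows)
    if (!is.finite(loss)) stop("training diverged (non-finite loss)")
    r <- .sgd_step(model$params, vel, gacc, sched$lr, sched$momentum)
    model$params <- r$p; vel <- r$v
    win <- c(win, loss)
    if (it %% sched$eval_every == 0L || it == iters) {
      ck <- mean(win)
      history <- rbind(history,
                       data.frame(phase = phase, iter = it, loss = ck))
      win <- c()
      if (check_converge) {
        if (ck < best - sched$min_delta) {
          best <- ck; stale <- 0L
        } else stale <- stale + 1L
        if (stale >= sched$patience) break
      }
    }
  }
  list(model = model, vel = vel, history = history)
}

#' Train a V-Net
#'
#' Phase 1 pretrains on the top-k foreground-ratio patches with the
#' class-weighted cross-entropy loss; phase 2 fine-tunes on the complete
#' patch grid of the training set until the checkpointed loss stops
#' improving (patience rule). Deterministic given the seed.
#'
#' @param model an untrained `vnet` from [build_vnet()].
#' @param inputs list of input arrays `(nx, ny, nz, C)`, one per training
#'   volume, channels already normalised.
#' @param targets list of binary 3D label arrays.
#' @param schedule a [training_schedule()].
#' @param seed integer seed controlling batch sampling.
#' @return The trained `vnet`, with a `history` data.frame of checkpoint
#'   losses and the class weights used.
#' @export
train_vnet <- function(model, inputs, targets, schedule = training_schedule(),
                       seed = 1L) {
  stopifnot(length(inputs) == length(targets))
  all_t <- unlist(lapply(targets, as.numeric))
  if (all(all_t == 0) || all(all_t == 1))
    stop("training set must contain both classes")
  ps_all <- extract_patches(targets, size = schedule$patch_size,
                            overlap = schedule$overlap)
  ps_top <- select_top_patches(ps_all, k = schedule$top_k)
  # inverse-frequency weights over the balanced pretraining pool: this is
  # the label universe the network actually sees, and it keeps the
  # foreground weight from exploding on whole-body volumes where lesions
  # are a fraction of a percent
  npos <- sum(ps_top$ratio * ps_top$sx * ps_top$sy * ps_top$sz)
  ntot <- sum(ps_top$sx * ps_top$sy * ps_top$sz)
  weights <- if (npos > 0 && npos < ntot)
    c(ntot / (2 * (ntot - npos)), ntot / (2 * npos)) else class_weights(all_t)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  history <- data.frame(phase = character(), iter = integer(),
                        loss = numeric())
  vel <- NULL
  r <- .run_phase(model, vel, inputs, targets, ps_top, weights, schedule,
                  schedule$pretrain_iters, "pretrain", history)
  r <- .run_phase(r$model, r$vel, inputs, targets, ps_all, weights, schedule,
                  schedule$max_finetune_iters, "finetune", r$history,
                  check_converge = TRUE)
  model <- r$model
  model$trained <- TRUE
  model$history <- r$history
  model$class_weights <- weights
  model
}

#' Train a W-Net cascade
#'
#' Stage 1 learns the skeleton mask from CT; stage 2 then learns the
#' lesion mask from CT + PET + the frozen stage-1 prediction.
#'
#' @param model a `wnet` from [build_wnet()].
#' @param ct,pet lists of normalised 3D arrays (one per volume).
#' @param bone_targets list of binary skeleton masks.
#' @param lesion_targets list of binary lesion masks.
#' @param schedule a [training_schedule()] for the lesion stage.
#' @param seed integer seed.
#' @param stage1_schedule optional separate schedule for the skeleton
#'   stage (it converges much faster than the lesion stage); defaults to
#'   `schedule`.
#' @return The trained `wnet`.
#' @export
train_wnet <- function(model, ct, pet, bone_targets, lesion_targets,
                       schedule = training_schedule(), seed = 1L,
                       stage1_schedule = schedule) {
  in1 <- lapply(ct, .as_input)
  model$stage1 <- train_vnet(model$stage1, in1, bone_targets,
                             stage1_schedule,
                             seed = derive_seed(seed, 21L))
  masks <- lapply(seq_along(ct), function(i) {
    pr <- predict_volume(model$stage1, in1[[i]],
                         patch_size = schedule$patch_size,
                         overlap = schedule$overlap)
    pr$mask * 1.0
  })
  in2 <- lapply(seq_along(ct), function(i) {
    x <- array(0, c(dim(ct[[i]]), 3L))
    x[, , , 1] <- ct[[i]]; x[, , , 2] <- pet[[i]]; x[, , , 3] <- masks[[i]]
    x
  })
  model$stage2 <- train_vnet(model$stage2, in2, lesion_targets, schedule,
                             seed = derive_seed(seed, 22L))
  model$trained <- TRUE
  model
}

#' Sliding-window whole-volume prediction
#'
#' Tiles the volume with the training patch size and overlap, averages
#' overlapping logits, and thresholds the sigmoid probability at 0.5.
#'
#' @param model a trained `vnet` or `wnet`.
#' @param x for a `vnet`: input array `(nx, ny, nz, C)`. For a `wnet`:
#'   a list with elements `ct` and `pet` (3D arrays, normalised).
#' @param patch_size,overlap tiling parameters (defaults 64 and 5).
#' @return For a `vnet`: list with `prob`, `mask`, `logits`. For a
#'   `wnet`: additionally `bone_mask` from stage 1.
#' @export
predict_volume <- function(model, x, patch_size = 64L, overlap = 5L) {
  UseMethod("predict_volume")
}

#' @export
predict_volume.vnet <- function(model, x, patch_size = 64L, overlap = 5L) {
  if (!isTRUE(model$trained))
    warning("model has not been trained; predictions are from random weights")
  x <- .as_input(x)
  d <- dim(x)[1:3]
  dummy <- array(0L, d)
  ps <- extract_patches(dummy, size = patch_size, overlap = overlap)
  lsum <- array(0, d); cnt <- array(0, d)
  for (i in seq_len(nrow(ps))) {
    xs <- ps$x[i]:(ps$x[i] + ps$sx[i] - 1L)
    ys <- ps$y[i]:(ps$y[i] + ps$sy[i] - 1L)
    zs <- ps$z[i]:(ps$z[i] + ps$sz[i] - 1L)
    lg <- vnet_forward(model, x[xs, ys, zs, , drop = FALSE])
    lsum[xs, ys, zs] <- lsum[xs, ys, zs] + lg
    cnt[xs, ys, zs] <- cnt[xs, ys, zs] + 1
  }
  logits <- lsum / cnt
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, mask = prob > 0.5, logits = logits)
}

#' @export
predict_volume.wnet <- function(model, x, patch_size = 64L, overlap = 5L) {
  if (!is.list(x) || is.null(x$ct) || is.null(x$pet))
    stop("wnet prediction needs list(ct = ..., pet = ...)")
  p1 <- predict_volume(model$stage1, .as_input(x$ct), patch_size, overlap)
  bone <- p1$prob > model$threshold
  xin <- array(0, c(dim(x$ct), 3L))
  xin[, , , 1] <- x$ct; xin[, , , 2] <- x$pet; xin[, , , 3] <- bone * 1.0
  p2 <- predict_volume(model$stage2, xin, patch_size, overlap)
  c(p2, list(bone_mask = bone))
}
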