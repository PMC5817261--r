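#' Inverse-frequency class weights
#'
#' Weights are inversely proportional to the voxel count of each class and
#' normalised so that `sum(w_c * n_c) = N`, keeping the weighted loss on
#' the same scale as the unweighted one. With counts `(n0, n1)` this gives
#' `w_c = N / (2 * n_c)`.
#'
#' @param labels binary array/vector of ground-truth labels.
#' @return Numeric vector `c(w0, w1)`. If a class is absent, falls back to
#'   unweighted `c(1, 1)` with a warning.
#' @export
class_weights <- function(labels) {
  n1 <- sum(labels == 1)
  n0 <- length(labels) - n1
  if (n0 == 0 || n1 == 0) {
    warning("one class is absent; falling back to unweighted loss")
    return(c(1, 1))
  }
  N <- n0 + n1
  c(N / (2 * n0), N / (2 * n1))
}

#' Class-weighted binary cross-entropy loss
#'
#' `L = -(1/N) * sum_i w_i * (t_i log p_i + (1 - t_i) log(1 - p_i))` with
#' `w_i` the weight of voxel `i`'s class. Probabilities are clipped to
#' `[eps, 1 - eps]` for numerical stability.
#'
#' @param pred array of foreground probabilities.
#' @param truth binary array, same shape.
#' @param weights per-class weights `c(w0, w1)`, e.g. [class_weights()].
#' @param eps clipping constant (default 1e-7).
#' @return Scalar loss (>= 0).
#' @export
weighted_cross_entropy <- function(pred, truth, weights = c(1, 1),
                                   eps = 1e-7) {
  if (length(pred) != length(truth))
    stop("pred and truth must have the same shape")
  if (any(is.na(pred))) stop("pred contains NA/NaN")
  p <- pmin(pmax(as.numeric(pred), eps), 1 - eps)
  t <- as.numeric(truth)
  w <- ifelse(t == 1, weights[2], weights[1])
  -mean(w * (t * log(p) + (1 - t) * log(1 - p)))
}

# gradient of the weighted BCE w.r.t. the logit z (p = sigmoid(z)):
# dL/dz_i = w_i * (p_i - t_i) / N
wce_logit_grad <- function(logits, truth, weights) {
  p <- 1 / (1 + exp(-logits))
  t <- as.numeric(truth)
  w <- ifelse(t == 1, weights[2], weights[1])
  g <- w * (p - t) / length(t)
  dim(g) <- dim(logits)
  g
}

# loss evaluated directly from logits (numerically stable)
wce_from_logits <- function(logits, truth, weights, eps = 1e-7) {
  p <- 1 / (1 + exp(-as.numeric(logits)))
  weighted_cross_entropy(p, truth, weights, eps = eps)
}
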