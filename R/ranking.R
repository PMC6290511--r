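# Feature ranking by back-propagating absolute connection-weight shares.
#
# For one dense layer, input k's contribution share toward output neuron j is
# |w_jk| / sum_k' |w_jk'|. Chaining these per-layer share matrices from the
# head back to the inputs sums the share product over every input-to-output
# path; activations and biases play no part. Column normalization makes every
# contribution vector sum to 1 (conservation).

#' Per-layer contribution shares
#'
#' Entry (k, j) is input neuron k's share of output neuron j's incoming
#' absolute weight, `|w_jk| / sum_k' |w_jk'|`. Biases are ignored. A column
#' whose weight row is entirely zero is set to the uniform share `1/fan_in`
#' so columns always sum to 1.
#'
#' @param layer A [dense_layer()] (or a bare weight matrix, fan_out x fan_in).
#' @return Nonnegative `fan_in x fan_out` matrix with unit column sums.
#' @export
layer_contributions <- function(layer) {
  W <- if (inherits(layer, "dense_layer") || is.list(layer)) layer$W else layer
  A <- abs(t(W))                      # fan_in x fan_out
  cs <- colSums(A)
  zero <- cs == 0
  if (any(zero)) {
    A[, zero] <- 1 / nrow(A)
    cs[zero] <- 1
  }
  sweep(A, 2L, cs, "/")
}

# aggregate a (possibly multi-output) head into one normalized share column
head_contribution_column <- function(head) {
  w <- colSums(abs(head$W))           # sum |weights| across output units
  if (sum(w) == 0) rep(1 / length(w), length(w)) else w / sum(w)
}

#' Propagate contribution shares from a head back to the inputs
#'
#' Chains the per-layer contribution matrices
#' `C_input = C_1 %*% C_2 %*% ... %*% c_head`, which equals summing the share
#' product `C_kj * C_jy` over all paths from each input to the output. For a
#' multi-output (softmax) head the per-output absolute weights are first
#' summed into one normalized column. The result is nonnegative and sums
#' to 1.
#'
#' @param subnet A [subnetwork()].
#' @param head A [task_head()] whose input dimension matches the subnetwork
#'   output.
#' @return Numeric vector of per-input contribution shares (sums to 1).
#' @export
propagate_contributions <- function(subnet, head) {
  if (ncol(head$W) != subnet_output_dim(subnet)) {
    stop("propagate_contributions: head dimension does not match subnetwork output",
         call. = FALSE)
  }
  v <- head_contribution_column(head)
  for (t in rev(seq_along(subnet$layers))) {
    v <- layer_contributions(subnet$layers[[t]]) %*% v
  }
  drop(v)
}

#' Rank input features by combined contribution to the primary target
#'
#' Computes each feature's contribution share through the primary-specific
#' branch and through the shared branch (both read out by the primary head),
#' then combines the two vectors with the fusion weights
#' `combined = a1 * specific + a2 * shared`, where (a1, a2) are the
#' per-sample fusion weights averaged over a reference dataset (typically
#' the training set). Features are returned sorted by descending combined
#' contribution.
#'
#' @param model A `gatan_model` (or `gatan_train` bundle, whose stored
#'   feature scaling is then applied to the reference data).
#' @param reference A [gatan_dataset()] (or feature matrix) used to average
#'   the per-sample fusion weights; must be nonempty.
#' @return Tibble with columns `feature`, `specific`, `shared`, `combined`,
#'   `rank`; `combined` sums to 1.
#' @export
rank_features <- function(model, reference) {
  scaling <- NULL
  if (inherits(model, "gatan_train") || inherits(model, "gatan_fit")) {
    scaling <- model$scaling
    model <- model$model
  }
  X <- if (inherits(reference, "gatan_dataset")) reference$X else as.matrix(reference)
  if (is.null(dim(X)) || nrow(X) == 0L) {
    stop("rank_features: reference dataset must be nonempty", call. = FALSE)
  }
  X <- standardize_apply(X, scaling)
  fw <- model_forward_batch(model, X)
  a1 <- mean(fw$fp$w1)
  spec <- propagate_contributions(model$primary, model$primary_head)
  shar <- propagate_contributions(model$shared, model$primary_head)
  combined <- a1 * spec + (1 - a1) * shar
  out <- tibble::tibble(feature = model$feature_names,
                        specific = spec, shared = shar, combined = combined)
  out <- dplyr::arrange(out, dplyr::desc(.data$combined))
  out$rank <- seq_len(nrow(out))
  attr(out, "a1") <- a1
  out
}

#' Contribution of features toward one auxiliary target
#'
#' The analogous ranking through an auxiliary branch and its head, combined
#' with that task's averaged (b1, b2) fusion weights.
#'
#' @inheritParams rank_features
#' @param task Index of the auxiliary task.
#' @return Tibble as in [rank_features()].
#' @export
rank_features_aux <- function(model, reference, task = 1L) {
  scaling <- NULL
  if (inherits(model, "gatan_train") || inherits(model, "gatan_fit")) {
    scaling <- model$scaling
    model <- model$model
  }
  stopifnot(task >= 1L, task <= length(model$aux))
  X <- if (inherits(reference, "gatan_dataset")) reference$X else as.matrix(reference)
  X <- standardize_apply(X, scaling)
  fw <- model_forward_batch(model, X)
  b1 <- mean(fw$fa[[task]]$w1)
  spec <- propagate_contributions(model$aux[[task]], model$aux_heads[[task]])
  shar <- propagate_contributions(model$shared, model$aux_heads[[task]])
  combined <- b1 * spec + (1 - b1) * shar
  out <- tibble::tibble(feature = model$feature_names,
                        specific = spec, shared = shar, combined = combined)
  out <- dplyr::arrange(out, dplyr::desc(.data$combined))
  out$rank <- seq_len(nrow(out))
  attr(out, "a1") <- b1
  out
}
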