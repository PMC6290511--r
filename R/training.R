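# ---- datasets ---------------------------------------------------------------

task_link_for <- function(type) {
  switch(type,
    continuous = "identity",
    binary = "sigmoid",
    categorical = "softmax",
    stop("unknown task type '", type, "'", call. = FALSE)
  )
}

check_target <- function(y, type, what) {
  if (type == "categorical") {
    if (!is.matrix(y)) stop(what, ": categorical target must be a one-hot matrix",
                            call. = FALSE)
    if (anyNA(y)) stop(what, ": missing values in target", call. = FALSE)
    if (any(abs(rowSums(y) - 1) > 1e-12)) {
      stop(what, ": one-hot rows must sum to 1", call. = FALSE)
    }
  } else {
    y <- as.numeric(y)
    if (anyNA(y)) stop(what, ": missing values in target", call. = FALSE)
    if (type == "binary" && !all(y %in% c(0, 1))) {
      stop(what, ": binary target must be coded 0/1", call. = FALSE)
    }
  }
  y
}

#' Assemble a multi-task dataset
#'
#' Bundles a feature matrix, the primary target and any auxiliary targets
#' with their task types. Continuous targets are numeric vectors; binary
#' targets are 0/1 vectors (sigmoid head); categorical targets are one-hot
#' matrices (softmax head). No missing values are allowed.
#'
#' @param X Numeric matrix or data frame, one row per sample.
#' @param y_primary Primary target (vector, or one-hot matrix if categorical).
#' @param y_aux List of auxiliary targets (possibly empty).
#' @param primary_type `"continuous"`, `"binary"` or `"categorical"`.
#' @param aux_types Character vector of task types, one per auxiliary target.
#' @param feature_names Optional column names (defaults to `colnames(X)`).
#' @return A `gatan_dataset` object.
#' @export
gatan_dataset <- function(X, y_primary, y_aux = list(),
                          primary_type = "continuous",
                          aux_types = rep("continuous", length(y_aux)),
                          feature_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("gatan_dataset: missing values in X", call. = FALSE)
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(X)))
  }
  stopifnot(length(feature_names) == ncol(X))
  colnames(X) <- feature_names
  if (length(y_aux) != length(aux_types)) {
    stop("gatan_dataset: aux_types must match y_aux in length", call. = FALSE)
  }
  y_primary <- check_target(y_primary, primary_type, "primary target")
  n_of <- function(y) if (is.matrix(y)) nrow(y) else length(y)
  if (n_of(y_primary) != nrow(X)) {
    stop("gatan_dataset: primary target length must equal nrow(X)", call. = FALSE)
  }
  y_aux <- purrr::map2(y_aux, seq_along(y_aux), function(y, k) {
    y <- check_target(y, aux_types[[k]], paste0("auxiliary target ", k))
    if (n_of(y) != nrow(X)) {
      stop("gatan_dataset: auxiliary target ", k, " length must equal nrow(X)",
           call. = FALSE)
    }
    y
  })
  structure(list(X = X, y_primary = y_primary, y_aux = y_aux,
                 primary_type = primary_type, aux_types = as.character(aux_types),
                 feature_names = feature_names),
            class = "gatan_dataset")
}

#' @export
print.gatan_dataset <- function(x, ...) {
  cat("<gatan_dataset> n = ", nrow(x$X), ", p = ", ncol(x$X),
      "; primary: ", x$primary_type,
      if (length(x$y_aux)) paste0("; aux: ", paste(x$aux_types, collapse = ", "))
      else "; no auxiliary tasks", "\n", sep = "")
  invisible(x)
}

dataset_subset <- function(data, idx) {
  sub <- function(y) if (is.matrix(y)) y[idx, , drop = FALSE] else y[idx]
  gatan_dataset(data$X[idx, , drop = FALSE], sub(data$y_primary),
                lapply(data$y_aux, sub), data$primary_type, data$aux_types,
                data$feature_names)
}

#' Split a dataset into train / validation / test parts
#'
#' Seeded random partition into disjoint parts of exactly the requested
#' sizes; the union of the parts preserves the row multiset (up to order).
#' Works on a `gatan_dataset` or a data frame.
#'
#' @param data A `gatan_dataset` or data frame.
#' @param sizes Integer vector `c(n_train, n_val, n_test)`; must sum to at
#'   most the number of rows.
#' @param seed Integer seed.
#' @return Named list `train`, `val`, `test` of the same class as `data`.
#' @export
split_dataset <- function(data, sizes, seed = 1L) {
  n <- if (inherits(data, "gatan_dataset")) nrow(data$X) else nrow(data)
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L || any(sizes < 0)) {
    stop("split_dataset: sizes must be three nonnegative integers", call. = FALSE)
  }
  if (sum(sizes) > n) {
    stop("split_dataset: sizes sum to ", sum(sizes), " but data has ", n, " rows",
         call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  idx <- list(train = perm[seq_len(sizes[1L])],
              val = perm[sizes[1L] + seq_len(sizes[2L])],
              test = perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])])
  take <- if (inherits(data, "gatan_dataset")) {
    function(i) dataset_subset(data, i)
  } else {
    function(i) data[i, , drop = FALSE]
  }
  lapply(idx, take)
}

# ---- losses -----------------------------------------------------------------

CE_EPS <- 1e-12

#' Squared loss for a regression task
#'
#' @param y,y_hat Finite numeric scalars (vectorized elementwise).
#' @return `(y - y_hat)^2`.
#' @export
squared_loss <- function(y, y_hat) (y - y_hat)^2

#' Cross-entropy loss for a classification task
#'
#' Standard cross-entropy `-sum(y * log(p_hat))` for a one-hot label and a
#' probability vector, with probabilities clipped at 1e-12 for numerical
#' safety.
#'
#' @param y One-hot numeric vector.
#' @param p_hat Probability vector of the same length, entries in (0, 1),
#'   summing to 1.
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(y, p_hat) {
  if (length(y) != length(p_hat)) {
    stop("cross_entropy_loss: length mismatch", call. = FALSE)
  }
  if (any(p_hat < 0) || any(p_hat > 1) || abs(sum(p_hat) - 1) > 1e-8) {
    stop("cross_entropy_loss: p_hat must be a probability vector", call. = FALSE)
  }
  if (abs(sum(y) - 1) > 1e-12 || any(y < 0)) {
    stop("cross_entropy_loss: y must be one-hot", call. = FALSE)
  }
  -sum(y * log(pmax(p_hat, CE_EPS)))
}

# sum of per-sample losses for one task, from the affine head values U (n x K)
task_loss_sum <- function(type, y, U) {
  switch(type,
    continuous = sum((y - U[, 1L])^2),
    binary = {
      p <- pmin(pmax(sigmoid(U[, 1L]), CE_EPS), 1 - CE_EPS)
      -sum(y * log(p) + (1 - y) * log(1 - p))
    },
    categorical = {
      P <- pmax(softmax_rows(U), CE_EPS)
      -sum(y * log(P))
    }
  )
}

# gradient of the summed task loss wrt the affine head values U (n x K)
task_loss_delta <- function(type, y, U) {
  switch(type,
    continuous = cbind(2 * (U[, 1L] - y)),
    binary = cbind(sigmoid(U[, 1L]) - y),
    categorical = softmax_rows(U) - y
  )
}

# ---- batched forward with cached intermediates ------------------------------

branch_forward <- function(subnet, X) {
  H <- vector("list", length(subnet$layers) + 1L)
  H[[1L]] <- X
  for (t in seq_along(subnet$layers)) {
    layer <- subnet$layers[[t]]
    H[[t + 1L]] <- sigmoid(tcrossprod(H[[t]], layer$W) +
                           rep(layer$b, each = nrow(X)))
  }
  H
}

fusion_batch <- function(Ht, Hs) {
  dot <- rowSums(Ht * Hs)
  nt <- sqrt(rowSums(Ht^2))
  ns <- sqrt(rowSums(Hs^2))
  denom <- nt * ns
  cosv <- ifelse(denom > 0, dot / denom, 0)
  w1 <- cosv / 2
  list(w1 = w1, w2 = 1 - w1, cosv = cosv, nt = nt, ns = ns, denom = denom)
}

head_affine <- function(head, H) {
  tcrossprod(H, head$W) + rep(head$b, each = nrow(H))
}

# full batched forward pass; caches everything backward needs
model_forward_batch <- function(model, X) {
  S <- branch_forward(model$shared, X)
  C <- branch_forward(model$primary, X)
  Hs <- S[[length(S)]]
  Hc <- C[[length(C)]]
  fp <- fusion_batch(Hc, Hs)
  Hfc <- fp$w1 * Hc + fp$w2 * Hs
  Uc <- head_affine(model$primary_head, Hfc)
  A <- lapply(model$aux, function(s) branch_forward(s, X))
  Ha <- lapply(A, function(h) h[[length(h)]])
  fa <- lapply(Ha, fusion_batch, Hs = Hs)
  Hfa <- purrr::map2(Ha, fa, function(h, f) f$w1 * h + f$w2 * Hs)
  Ua <- purrr::map2(model$aux_heads, Hfa, head_affine)
  list(S = S, C = C, A = A, Hs = Hs, Hc = Hc, Ha = Ha,
       fp = fp, fa = fa, Hfc = Hfc, Hfa = Hfa, Uc = Uc, Ua = Ua)
}

model_task_types <- function(model, data) {
  if (length(model$aux) != length(data$y_aux)) {
    stop("model has ", length(model$aux), " auxiliary tasks but data has ",
         length(data$y_aux), call. = FALSE)
  }
  invisible(TRUE)
}

#' Joint multi-task training objective
#'
#' The sum over samples of the primary-task loss plus `omega` times the sum
#' of every auxiliary-task loss. Each task uses the loss matching its type:
#' squared loss for continuous targets, cross-entropy for binary/categorical.
#'
#' @param model A `gatan_model` whose auxiliary task count matches `data`.
#' @param data A [gatan_dataset()].
#' @param omega Nonnegative auxiliary-task weight (default 1).
#' @return Nonnegative scalar.
#' @export
joint_objective <- function(model, data, omega = 1) {
  stopifnot(omega >= 0)
  model_task_types(model, data)
  fw <- model_forward_batch(model, data$X)
  obj <- task_loss_sum(data$primary_type, data$y_primary, fw$Uc)
  for (k in seq_along(data$y_aux)) {
    obj <- obj + omega * task_loss_sum(data$aux_types[[k]], data$y_aux[[k]],
                                       fw$Ua[[k]])
  }
  obj
}

# ---- exact gradient ---------------------------------------------------------

# d a1 / d Ht and d a1 / d Hs for a batch; rows where a norm vanishes get 0
fusion_grad_batch <- function(Ht, Hs, f) {
  ok <- as.numeric(f$denom > 0)
  denom <- ifelse(f$denom > 0, f$denom, 1)
  nt2 <- ifelse(f$nt > 0, f$nt^2, 1)
  ns2 <- ifelse(f$ns > 0, f$ns^2, 1)
  list(dHt = 0.5 * ok * (Hs / denom - f$cosv * Ht / nt2),
       dHs = 0.5 * ok * (Ht / denom - f$cosv * Hs / ns2))
}

# backprop G (n x d at branch output) through a subnetwork's layers
branch_backward <- function(subnet, H, G) {
  L <- length(subnet$layers)
  grads <- vector("list", L)
  for (t in L:1) {
    A <- H[[t + 1L]]
    D <- G * A * (1 - A)
    grads[[t]] <- list(W = crossprod(D, H[[t]]), b = colSums(D))
    if (t > 1L) G <- D %*% subnet$layers[[t]]$W
  }
  grads
}

#' Exact gradient of the joint objective
#'
#' Reverse-mode differentiation of [joint_objective()] with respect to every
#' parameter, including the flow of gradients through the per-sample fusion
#' weights (which depend on the parameters via the cosine of the branch
#' representations). Matches central finite differences.
#'
#' @inheritParams joint_objective
#' @return A list with the same nesting as the model: `shared`, `primary`,
#'   `aux` (lists of per-layer `W`/`b` gradients), `primary_head`,
#'   `aux_heads`.
#' @export
gatan_gradient <- function(model, data, omega = 1) {
  stopifnot(omega >= 0)
  model_task_types(model, data)
  fw <- model_forward_batch(model, data$X)
  Hs <- fw$Hs; Hc <- fw$Hc

  # primary head
  delta_c <- task_loss_delta(data$primary_type, data$y_primary, fw$Uc)
  g_head_c <- list(W = crossprod(delta_c, fw$Hfc), b = colSums(delta_c))
  G_fc <- delta_c %*% model$primary_head$W

  # primary fusion
  fg <- fusion_grad_batch(Hc, Hs, fw$fp)
  s <- rowSums(G_fc * (Hc - Hs))
  G_c <- fw$fp$w1 * G_fc + s * fg$dHt
  G_s <- fw$fp$w2 * G_fc + s * fg$dHs

  # auxiliary heads and fusions (loss scaled by omega)
  g_heads_a <- vector("list", length(model$aux))
  g_aux <- vector("list", length(model$aux))
  for (k in seq_along(model$aux)) {
    delta_a <- omega * task_loss_delta(data$aux_types[[k]], data$y_aux[[k]],
                                       fw$Ua[[k]])
    g_heads_a[[k]] <- list(W = crossprod(delta_a, fw$Hfa[[k]]),
                           b = colSums(delta_a))
    G_fa <- delta_a %*% model$aux_heads[[k]]$W
    fga <- fusion_grad_batch(fw$Ha[[k]], Hs, fw$fa[[k]])
    sa <- rowSums(G_fa * (fw$Ha[[k]] - Hs))
    G_a <- fw$fa[[k]]$w1 * G_fa + sa * fga$dHt
    G_s <- G_s + fw$fa[[k]]$w2 * G_fa + sa * fga$dHs
    g_aux[[k]] <- branch_backward(model$aux[[k]], fw$A[[k]], G_a)
  }

  list(shared = branch_backward(model$shared, fw$S, G_s),
       primary = branch_backward(model$primary, fw$C, G_c),
       aux = g_aux,
       primary_head = g_head_c,
       aux_heads = g_heads_a)
}

# ---- parameter vector helpers -----------------------------------------------

#' Flatten model parameters (or a gradient) to a numeric vector
#'
#' Fixed traversal order: shared layers, primary layers, auxiliary layers,
#' primary head, auxiliary heads; within a layer, weights then biases.
#'
#' @param model A `gatan_model` or the gradient list from [gatan_gradient()].
#' @return Numeric vector.
#' @export
flatten_params <- function(model) {
  lay <- function(l) c(as.numeric(l$W), l$b)
  sub <- function(s) unlist(lapply(if (is.null(s$layers)) s else s$layers, lay))
  c(sub(model$shared), sub(model$primary),
    unlist(lapply(model$aux, sub)),
    lay(model$primary_head),
    unlist(lapply(model$aux_heads, lay)))
}

#' Rebuild a model from a flat parameter vector
#'
#' Inverse of [flatten_params()] for a template model of identical shape.
#'
#' @param model Template `gatan_model`.
#' @param theta Numeric vector of length `length(flatten_params(model))`.
#' @return A `gatan_model`.
#' @export
unflatten_params <- function(model, theta) {
  pos <- 0L
  take <- function(k) {
    out <- theta[pos + seq_len(k)]
    pos <<- pos + k
    out
  }
  lay <- function(l) {
    l$W[] <- take(length(l$W))
    l$b <- take(length(l$b))
    l
  }
  sub <- function(s) {
    s$layers <- lapply(s$layers, lay)
    s
  }
  model$shared <- sub(model$shared)
  model$primary <- sub(model$primary)
  model$aux <- lapply(model$aux, sub)
  model$primary_head <- lay(model$primary_head)
  model$aux_heads <- lapply(model$aux_heads, lay)
  stopifnot(pos == length(theta))
  model
}

# ---- training ---------------------------------------------------------------

#' Training configuration
#'
#' @param omega Nonnegative auxiliary-task weight in the joint objective
#'   (default 1).
#' @param learning_rate Positive constant step size applied to the
#'   per-sample-averaged gradient (default 0.05).
#' @param epochs Number of full-batch gradient steps (default 2000).
#' @param standardize Z-score the feature columns using training-set
#'   statistics (default TRUE)?
#' @param seed Integer seed recorded with the run.
#' @param early_stop_patience Stop when the primary-task validation loss has
#'   not improved for this many epochs and return the best parameters;
#'   0 disables (default 100). Ignored when no validation set is given.
#' @return A `train_config` list.
#' @export
train_config <- function(omega = 1, learning_rate = 0.05, epochs = 2000L,
                         standardize = TRUE, seed = 1L,
                         early_stop_patience = 100L) {
  stopifnot(omega >= 0, learning_rate > 0, epochs >= 0, early_stop_patience >= 0)
  structure(list(omega = omega, learning_rate = learning_rate,
                 epochs = as.integer(epochs), standardize = standardize,
                 seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience)),
            class = "train_config")
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

standardize_apply <- function(X, scaling) {
  if (is.null(scaling)) return(X)
  sweep(sweep(X, 2L, scaling$mean, "-"), 2L, scaling$sd, "/")
}

# primary-task validation loss (mean per sample, on the scale used for early
# stopping: MSE for regression, cross-entropy for classification)
primary_val_loss <- function(model, data) {
  fw <- model_forward_batch(model, data$X)
  task_loss_sum(data$primary_type, data$y_primary, fw$Uc) / nrow(data$X)
}

apply_update <- function(model, grad, step) {
  upd_lay <- function(l, g) {
    l$W <- l$W - step * g$W
    l$b <- l$b - step * g$b
    l
  }
  upd_sub <- function(s, g) {
    s$layers <- purrr::map2(s$layers, g, upd_lay)
    s
  }
  model$shared <- upd_sub(model$shared, grad$shared)
  model$primary <- upd_sub(model$primary, grad$primary)
  model$aux <- purrr::map2(model$aux, grad$aux, upd_sub)
  model$primary_head <- upd_lay(model$primary_head, grad$primary_head)
  model$aux_heads <- purrr::map2(model$aux_heads, grad$aux_heads, upd_lay)
  model
}

#' Train a model by full-batch gradient descent
#'
#' Runs plain gradient descent on the joint objective with a constant
#' learning rate applied to the per-sample-averaged gradient. When a
#' validation set and a positive patience are given, training stops after
#' `early_stop_patience` epochs without improvement of the primary-task
#' validation loss and the best-epoch parameters are returned.
#' Standardization statistics are fit on the training set only and stored
#' with the result. Fully deterministic for a given model and data.
#'
#' @param model Initial `gatan_model`.
#' @param train A [gatan_dataset()] for training.
#' @param val Optional [gatan_dataset()] for validation-based early stopping.
#' @param cfg A [train_config()].
#' @return A `gatan_train` list: `model` (trained), `report` (a
#'   `train_report`), `scaling` (feature means/sds or NULL).
#' @export
train_gatan <- function(model, train, val = NULL, cfg = train_config()) {
  if (nrow(train$X) == 0L) stop("train_gatan: empty training set", call. = FALSE)
  model_task_types(model, train)
  scaling <- NULL
  if (isTRUE(cfg$standardize)) {
    scaling <- standardize_fit(train$X)
    train$X <- standardize_apply(train$X, scaling)
    if (!is.null(val)) val$X <- standardize_apply(val$X, scaling)
  }
  n <- nrow(train$X)
  step <- cfg$learning_rate / n
  objective <- numeric(0)
  val_loss <- numeric(0)
  best <- list(loss = Inf, model = model, epoch = 0L)
  use_val <- !is.null(val) && cfg$early_stop_patience > 0L
  epoch <- 0L
  while (epoch < cfg$epochs) {
    epoch <- epoch + 1L
    grad <- gatan_gradient(model, train, cfg$omega)
    model <- apply_update(model, grad, step)
    objective[epoch] <- joint_objective(model, train, cfg$omega)
    if (!is.null(val)) {
      val_loss[epoch] <- primary_val_loss(model, val)
      if (val_loss[epoch] < best$loss) {
        best <- list(loss = val_loss[epoch], model = model, epoch = epoch)
      }
      if (use_val && epoch - best$epoch >= cfg$early_stop_patience) break
    }
  }
  selected <- if (use_val && best$epoch > 0L) best$epoch else epoch
  final_model <- if (use_val && best$epoch > 0L) best$model else model
  mean_a1 <- if (n > 0L) {
    mean(model_forward_batch(final_model, train$X)$fp$w1)
  } else NA_real_
  report <- structure(list(objective = objective, val_loss = val_loss,
                           epoch_selected = selected, epochs_run = epoch,
                           mean_a1 = mean_a1, config = cfg),
                      class = "train_report")
  structure(list(model = final_model, report = report, scaling = scaling),
            class = "gatan_train")
}

#' @export
print.train_report <- function(x, ...) {
  cat("<train_report> ", x$epochs_run, " epoch(s); selected epoch ",
      x$epoch_selected, "; final objective ",
      if (length(x$objective)) format(x$objective[length(x$objective)]) else "NA",
      "; mean a1 ", format(x$mean_a1), "\n", sep = "")
  invisible(x)
}

# predictions (link scale) for a trained bundle or bare model
predict_batch <- function(model, X, scaling = NULL) {
  X <- standardize_apply(as.matrix(X), scaling)
  fw <- model_forward_batch(model, X)
  link_out <- function(type, U) {
    switch(type,
      continuous = U[, 1L],
      binary = sigmoid(U[, 1L]),
      categorical = softmax_rows(U)
    )
  }
  # types are recovered from the head links
  type_of <- function(head) switch(head$link, identity = "continuous",
                                   sigmoid = "binary", categorical = ,
                                   softmax = "categorical")
  list(primary = link_out(type_of(model$primary_head), fw$Uc),
       aux = purrr::map2(model$aux_heads, fw$Ua,
                         function(h, U) link_out(type_of(h), U)),
       mean_a1 = mean(fw$fp$w1))
}
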