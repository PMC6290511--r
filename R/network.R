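# ---- low-level building blocks ----------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Construct a dense layer
#'
#' A dense layer is an affine map `h -> W h + b` with a `fan_out x fan_in`
#' weight matrix and a `fan_out` bias vector.
#'
#' @param weights Numeric matrix, `fan_out x fan_in`.
#' @param biases Numeric vector of length `fan_out`.
#' @return A `dense_layer` object (list with `W`, `b`).
#' @export
dense_layer <- function(weights, biases) {
  weights <- as.matrix(weights)
  biases <- as.numeric(biases)
  if (nrow(weights) != length(biases)) {
    stop("dense_layer: weight row count (", nrow(weights),
         ") must equal bias length (", length(biases), ")", call. = FALSE)
  }
  if (!all(is.finite(weights)) || !all(is.finite(biases))) {
    stop("dense_layer: all entries must be finite", call. = FALSE)
  }
  structure(list(W = weights, b = biases), class = "dense_layer")
}

#' Construct a subnetwork (stack of dense layers + elementwise activation)
#'
#' @param layers List of [dense_layer()] objects; consecutive layers must be
#'   dimension compatible.
#' @param role One of `"shared"`, `"primary"`, `"auxiliary"`.
#' @param activation Name of the elementwise nonlinearity; only `"sigmoid"`
#'   is supported.
#' @return A `subnetwork` object.
#' @export
subnetwork <- function(layers, role = c("shared", "primary", "auxiliary"),
                       activation = "sigmoid") {
  role <- match.arg(role)
  if (!identical(activation, "sigmoid")) {
    stop("subnetwork: unsupported activation '", activation, "'", call. = FALSE)
  }
  if (length(layers) < 1L) stop("subnetwork: needs at least one layer", call. = FALSE)
  for (t in seq_along(layers)[-1]) {
    if (ncol(layers[[t]]$W) != nrow(layers[[t - 1L]]$W)) {
      stop("subnetwork: layer ", t, " fan_in (", ncol(layers[[t]]$W),
           ") does not match layer ", t - 1L, " fan_out (",
           nrow(layers[[t - 1L]]$W), ")", call. = FALSE)
    }
  }
  structure(list(layers = layers, role = role, activation = activation),
            class = "subnetwork")
}

subnet_input_dim <- function(subnet) ncol(subnet$layers[[1L]]$W)
subnet_output_dim <- function(subnet) nrow(subnet$layers[[length(subnet$layers)]]$W)

#' Construct a task head
#'
#' A linear readout on the fused representation followed by a link function.
#' Identity for regression; sigmoid for binary classification; softmax for
#' K-class classification (then `weights` has K rows and `bias` length K).
#'
#' @param weights Numeric matrix `K x representation_dim` (a vector is taken
#'   as a single row).
#' @param bias Numeric vector of length K.
#' @param link One of `"identity"`, `"sigmoid"`, `"softmax"`.
#' @return A `task_head` object.
#' @export
task_head <- function(weights, bias, link = c("identity", "sigmoid", "softmax")) {
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1L)
  bias <- as.numeric(bias)
  link <- match.arg(link)
  if (nrow(weights) != length(bias)) {
    stop("task_head: weight rows must equal bias length", call. = FALSE)
  }
  if (link %in% c("identity", "sigmoid") && nrow(weights) != 1L) {
    stop("task_head: ", link, " link requires a single output unit", call. = FALSE)
  }
  structure(list(W = weights, b = bias, link = link), class = "task_head")
}

# seeded symmetric uniform init, scale 1/sqrt(fan_in)
init_dense <- function(fan_out, fan_in) {
  s <- 1 / sqrt(fan_in)
  dense_layer(matrix(stats::runif(fan_out * fan_in, -s, s), fan_out, fan_in),
              stats::runif(fan_out, -s, s))
}

init_subnet <- function(input_dim, hidden_dims, role) {
  dims <- c(input_dim, hidden_dims)
  layers <- lapply(seq_along(hidden_dims),
                   function(t) init_dense(dims[t + 1L], dims[t]))
  subnetwork(layers, role = role)
}

init_head <- function(rep_dim, link) {
  k <- if (identical(link, "softmax")) 2L else 1L
  s <- 1 / sqrt(rep_dim)
  task_head(matrix(stats::runif(k * rep_dim, -s, s), k, rep_dim),
            stats::runif(k, -s, s), link = link)
}

#' Initialize a multi-task auxiliary-task augmented network
#'
#' Builds the full model: one shared subnetwork, one primary-task subnetwork,
#' `num_aux` auxiliary subnetworks (all mapping
#' `input_dim -> hidden_dims[1] -> ... -> hidden_dims[length(hidden_dims)]`),
#' and one linear head per task. The last hidden dimension is the
#' representation dimension shared by every branch, as required by the
#' weighted-sum fusion. Weights are drawn from a seeded symmetric uniform
#' distribution with scale `1/sqrt(fan_in)`.
#'
#' The shared branch, primary branch and primary head consume the random
#' stream before any auxiliary component, so models that differ only in
#' `num_aux` share identical primary-side initial parameters for the same
#' seed.
#'
#' @param input_dim Number of input features (positive integer).
#' @param hidden_dims Integer vector of hidden-layer sizes; default `c(80, 40)`.
#' @param num_aux Number of auxiliary tasks (>= 0).
#' @param task_links Character vector of link names, one per task (primary
#'   first): `"identity"`, `"sigmoid"` or `"softmax"`. Recycled from
#'   `"identity"` if omitted.
#' @param seed Integer seed; identical seeds give bitwise-identical models.
#' @param feature_names Optional character vector of length `input_dim`.
#' @return A `gatan_model` object.
#' @examples
#' m <- init_model(5, c(8, 4), num_aux = 1, seed = 1)
#' length(forward(m, rnorm(5))$h_s)  # representation dimension 4
#' @export
init_model <- function(input_dim, hidden_dims = c(80L, 40L), num_aux = 0L,
                       task_links = NULL, seed = 1L, feature_names = NULL) {
  if (length(input_dim) != 1L || is.na(input_dim) || input_dim < 1) {
    stop("init_model: input_dim must be a positive integer", call. = FALSE)
  }
  if (length(hidden_dims) < 1L || any(hidden_dims < 1)) {
    stop("init_model: hidden_dims must be a nonempty vector of positive integers",
         call. = FALSE)
  }
  if (num_aux < 0) stop("init_model: num_aux must be >= 0", call. = FALSE)
  if (is.null(task_links)) task_links <- rep("identity", num_aux + 1L)
  if (length(task_links) != num_aux + 1L) {
    stop("init_model: task_links must have one entry per task (primary first)",
         call. = FALSE)
  }
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(input_dim))
  stopifnot(length(feature_names) == input_dim)

  rep_dim <- hidden_dims[length(hidden_dims)]
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))

  shared <- init_subnet(input_dim, hidden_dims, "shared")
  primary <- init_subnet(input_dim, hidden_dims, "primary")
  primary_head <- init_head(rep_dim, task_links[[1L]])
  aux <- list()
  aux_heads <- list()
  if (num_aux > 0L) {
    for (k in seq_len(num_aux)) {
      aux[[k]] <- init_subnet(input_dim, hidden_dims, "auxiliary")
      aux_heads[[k]] <- init_head(rep_dim, task_links[[k + 1L]])
    }
  }
  structure(list(shared = shared, primary = primary, aux = aux,
                 primary_head = primary_head, aux_heads = aux_heads,
                 feature_names = as.character(feature_names),
                 hidden_dims = as.integer(hidden_dims)),
            class = "gatan_model")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Drop the auxiliary branches of a model
#'
#' Returns the capacity-matched single-task model: same shared and primary
#' subnetworks and primary head, no auxiliary components. Used to compare a
#' multi-task fit against its single-task counterpart under identical
#' initialization.
#'
#' @param model A `gatan_model`.
#' @return A `gatan_model` with `num_aux = 0`.
#' @export
drop_aux <- function(model) {
  model$aux <- list()
  model$aux_heads <- list()
  model
}

#' @export
print.gatan_model <- function(x, ...) {
  cat("<gatan_model> ", subnet_input_dim(x$shared), " features -> hidden [",
      paste(x$hidden_dims, collapse = ", "), "], ",
      length(x$aux), " auxiliary task(s); primary link: ",
      x$primary_head$link, "\n", sep = "")
  invisible(x)
}

# ---- forward computation ----------------------------------------------------

#' Forward pass through one subnetwork
#'
#' Applies, per layer, the affine map followed by the elementwise sigmoid, and
#' returns the final hidden activation (the branch representation). Under the
#' sigmoid activation all outputs lie in (0, 1).
#'
#' @param subnet A [subnetwork()].
#' @param x Numeric feature vector (or `n x p` matrix of rows).
#' @return Representation vector (or `n x d` matrix).
#' @export
forward_subnetwork <- function(subnet, x) {
  h <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(h) != subnet_input_dim(subnet)) {
    stop("forward_subnetwork: input has ", ncol(h), " columns but subnetwork expects ",
         subnet_input_dim(subnet), call. = FALSE)
  }
  for (layer in subnet$layers) {
    h <- sigmoid(tcrossprod(h, layer$W) + rep(layer$b, each = nrow(h)))
  }
  if (is.matrix(x)) h else drop(h)
}

#' Cosine similarity of two vectors
#'
#' `v1 . v2 / (||v1|| ||v2||)`. If either vector has zero norm the similarity
#' is defined as 0 (all fusion weight then goes to the shared branch); this
#' case is unreachable under sigmoid activations but keeps the function total.
#'
#' @param v1,v2 Numeric vectors of equal length.
#' @return A scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    stop("cosine_similarity: vectors must have equal length", call. = FALSE)
  }
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(0)
  sum(v1 * v2) / (n1 * n2)
}

#' Convex fusion weights from cosine similarity
#'
#' The task-specific weight is half the cosine similarity of the two
#' representations, `w1 = cosd(h_task, h_shared) / 2`, and `w2 = 1 - w1`, so
#' the shared representation always contributes at least half. The same rule
#' yields the primary pair (a1, a2) and each auxiliary pair (b1, b2).
#'
#' @param h_task,h_shared Representation vectors of equal dimension.
#' @return Named numeric vector `c(w1, w2)` with `w1 + w2 == 1` exactly.
#' @export
fusion_weights <- function(h_task, h_shared) {
  w1 <- cosine_similarity(h_task, h_shared) / 2
  c(w1 = w1, w2 = 1 - w1)
}

#' Fuse a task-specific and the shared representation
#'
#' Weighted sum `w1 * h_task + w2 * h_shared` with weights from
#' [fusion_weights()]. A convex combination: every coordinate of the result
#' lies between its two parents.
#'
#' @inheritParams fusion_weights
#' @return Fused representation vector.
#' @export
fuse <- function(h_task, h_shared) {
  w <- fusion_weights(h_task, h_shared)
  w[[1L]] * h_task + w[[2L]] * h_shared
}

softmax_rows <- function(U) {
  U <- U - apply(U, 1L, max)
  E <- exp(U)
  E / rowSums(E)
}

#' Apply a task head to a fused representation
#'
#' Identity link returns the affine value; sigmoid returns a probability in
#' (0, 1); softmax returns a probability vector summing to 1.
#'
#' @param head A [task_head()].
#' @param h_fused Fused representation vector (or `n x d` matrix).
#' @return Prediction on the link scale: scalar/vector for identity and
#'   sigmoid, probability vector (or `n x K` matrix) for softmax.
#' @export
predict_head <- function(head, h_fused) {
  H <- if (is.matrix(h_fused)) h_fused else matrix(h_fused, nrow = 1L)
  if (ncol(H) != ncol(head$W)) {
    stop("predict_head: representation dimension mismatch", call. = FALSE)
  }
  U <- tcrossprod(H, head$W) + rep(head$b, each = nrow(H))
  out <- switch(head$link,
    identity = U[, 1L],
    sigmoid = sigmoid(U[, 1L]),
    softmax = softmax_rows(U),
    stop("predict_head: unknown link '", head$link, "'", call. = FALSE)
  )
  if (is.matrix(h_fused) || head$link == "softmax") out else out[[1L]]
}

#' Full forward pass of the multi-task model
#'
#' Computes the shared, primary and auxiliary representations, the per-sample
#' fusion weights, the fused representations and the per-task predictions on
#' the link scale.
#'
#' @param model A `gatan_model`.
#' @param x Feature vector of length `input_dim`.
#' @return A `gatan_trace` list with fields `h_s`, `h_c`, `h_a_list`,
#'   `fused_primary`, `fused_aux_list`, `fusion` (list with `a1`, `a2`,
#'   `b_pairs`), `prediction_primary`, `predictions_aux`.
#' @export
forward <- function(model, x) {
  if (length(x) != subnet_input_dim(model$shared)) {
    stop("forward: input length ", length(x), " does not match model input dimension ",
         subnet_input_dim(model$shared), call. = FALSE)
  }
  h_s <- forward_subnetwork(model$shared, x)
  h_c <- forward_subnetwork(model$primary, x)
  a <- fusion_weights(h_c, h_s)
  h_fc <- a[[1L]] * h_c + a[[2L]] * h_s
  h_a_list <- lapply(model$aux, forward_subnetwork, x = x)
  b_pairs <- lapply(h_a_list, fusion_weights, h_shared = h_s)
  h_fa_list <- purrr::map2(h_a_list, b_pairs,
                           function(h_a, b) b[[1L]] * h_a + b[[2L]] * h_s)
  structure(list(
    h_s = h_s, h_c = h_c, h_a_list = h_a_list,
    fused_primary = h_fc, fused_aux_list = h_fa_list,
    fusion = list(a1 = a[[1L]], a2 = a[[2L]], b_pairs = b_pairs),
    prediction_primary = predict_head(model$primary_head, h_fc),
    predictions_aux = purrr::map2(model$aux_heads, h_fa_list, predict_head)
  ), class = "gatan_trace")
}
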