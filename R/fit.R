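# Data-frame-first fitting interface.

`%||%` <- function(a, b) if (is.null(a)) b else a

one_hot <- function(x, levels = NULL) {
  x <- as.character(x)
  if (is.null(levels)) levels <- unique(x)   # first-occurrence order
  if (anyNA(match(x, levels))) {
    stop("unknown level(s): ",
         paste(setdiff(unique(x), levels), collapse = ", "), call. = FALSE)
  }
  Y <- matrix(0, length(x), length(levels), dimnames = list(NULL, levels))
  Y[cbind(seq_along(x), match(x, levels))] <- 1
  Y
}

infer_task_type <- function(v) {
  if (is.numeric(v)) {
    if (all(v %in% c(0, 1))) "binary" else "continuous"
  } else {
    lv <- unique(as.character(v))
    if (length(lv) == 2L) "binary" else "categorical"
  }
}

encode_target <- function(v, type, levels = NULL) {
  switch(type,
    continuous = list(y = as.numeric(v), levels = NULL),
    binary = {
      if (is.numeric(v)) {
        list(y = as.numeric(v), levels = levels %||% c("0", "1"))
      } else {
        lv <- levels %||% unique(as.character(v))
        list(y = as.numeric(match(as.character(v), lv) - 1L), levels = lv)
      }
    },
    categorical = {
      lv <- levels %||% unique(as.character(v))
      list(y = one_hot(v, lv), levels = lv)
    })
}

#' Convert a data frame to a multi-task dataset
#'
#' Picks the primary and auxiliary target columns out of a data frame; all
#' remaining numeric columns become features. Task types are inferred
#' (numeric -> continuous, 0/1 or two-level -> binary, more levels ->
#' categorical) unless given. Categorical levels are recorded in
#' first-occurrence order.
#'
#' @param data A data frame.
#' @param primary Name of the primary target column.
#' @param aux Character vector of auxiliary target column names.
#' @param primary_type,aux_types Optional explicit task types.
#' @param features Optional explicit feature column names (default: all
#'   other columns).
#' @param levels Optional named list of level orders for categorical/binary
#'   targets (used at predict time to reuse the training encoding).
#' @return A [gatan_dataset()] with an `encoding` attribute.
#' @export
as_gatan_dataset <- function(data, primary, aux = character(),
                             primary_type = NULL, aux_types = NULL,
                             features = NULL, levels = NULL) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(primary, aux), names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  features <- features %||% setdiff(names(data), c(primary, aux))
  X <- data[features]
  bad <- !vapply(X, is.numeric, logical(1L))
  if (any(bad)) {
    stop("non-numeric feature column(s): ",
         paste(features[bad], collapse = ", "), call. = FALSE)
  }
  primary_type <- primary_type %||% infer_task_type(data[[primary]])
  aux_types <- aux_types %||% vapply(data[aux], infer_task_type, character(1L))
  enc_p <- encode_target(data[[primary]], primary_type,
                         levels[[primary]] %||% NULL)
  enc_a <- lapply(seq_along(aux), function(k) {
    encode_target(data[[aux[k]]], aux_types[[k]], levels[[aux[k]]] %||% NULL)
  })
  ds <- gatan_dataset(as.matrix(X), enc_p$y, lapply(enc_a, `[[`, "y"),
                      primary_type = primary_type, aux_types = aux_types,
                      feature_names = features)
  lv <- c(stats::setNames(list(enc_p$levels), primary),
          stats::setNames(lapply(enc_a, `[[`, "levels"), aux))
  attr(ds, "encoding") <- list(primary = primary, aux = aux,
                               primary_type = primary_type,
                               aux_types = aux_types, levels = lv)
  ds
}

#' Fit an auxiliary-task augmented network to a data frame
#'
#' The main entry point: takes a data frame, the primary target column and
#' any auxiliary target columns, builds the multi-branch network (shared +
#' one branch per task, fused per sample by cosine-similarity weights) and
#' trains it by full-batch gradient descent on the joint objective.
#'
#' @param data Training data frame (one row per sample).
#' @param primary Name of the primary target column.
#' @param aux Character vector of auxiliary target column names (may be
#'   empty for a single-task fit).
#' @param hidden Hidden-layer sizes; default `c(80, 40)` (the last entry is
#'   the representation dimension).
#' @param omega Auxiliary-task weight in the joint objective (default 1).
#' @param learning_rate,epochs,standardize,early_stop_patience See
#'   [train_config()].
#' @param validation Optional validation data frame (same columns), or a
#'   fraction in (0, 1) to split off from `data`, used for early stopping.
#' @param seed Integer seed for initialization (and the validation split).
#' @param primary_type,aux_types Optional explicit task types.
#' @return A `gatan_fit` object with elements `model`, `report`, `scaling`,
#'   and the column/encoding bookkeeping. Methods: [predict.gatan_fit()],
#'   [tidy.gatan_fit()], [glance.gatan_fit()], [autoplot.gatan_fit()].
#' @examples
#' sim <- simulate_multitask(n = 60, p = 8, k_informative = 3, seed = 1)
#' fit <- gatan(sim$data, primary = "y", aux = "aux1",
#'              hidden = c(8, 4), epochs = 50, seed = 1)
#' predict(fit, sim$data)
#' @export
gatan <- function(data, primary, aux = character(), hidden = c(80L, 40L),
                  omega = 1, learning_rate = 0.05, epochs = 2000L,
                  standardize = TRUE, early_stop_patience = 100L,
                  validation = NULL, seed = 1L,
                  primary_type = NULL, aux_types = NULL) {
  val_frame <- NULL
  if (is.numeric(validation) && length(validation) == 1L && validation < 1) {
    n <- nrow(data)
    n_val <- max(1L, round(validation * n))
    parts <- split_dataset(as.data.frame(data), c(n - n_val, n_val, 0L),
                           seed = seed)
    data <- parts$train
    val_frame <- parts$val
  } else if (is.data.frame(validation)) {
    val_frame <- validation
  } else if (!is.null(validation)) {
    stop("validation must be NULL, a fraction, or a data frame", call. = FALSE)
  }

  ds <- as_gatan_dataset(data, primary, aux, primary_type, aux_types)
  enc <- attr(ds, "encoding")
  val_ds <- if (!is.null(val_frame)) {
    as_gatan_dataset(val_frame, primary, aux, enc$primary_type, enc$aux_types,
                     features = ds$feature_names, levels = enc$levels)
  }
  links <- vapply(c(enc$primary_type, enc$aux_types), task_link_for,
                  character(1L))
  model <- init_model(ncol(ds$X), hidden, num_aux = length(aux),
                      task_links = links, seed = seed,
                      feature_names = ds$feature_names)
  if (enc$primary_type == "categorical") {
    model$primary_head <- resize_head(model$primary_head,
                                      ncol(ds$y_primary), seed + 1L)
  }
  for (k in seq_along(aux)) {
    if (enc$aux_types[[k]] == "categorical") {
      model$aux_heads[[k]] <- resize_head(model$aux_heads[[k]],
                                          ncol(ds$y_aux[[k]]), seed + 1L + k)
    }
  }
  cfg <- train_config(omega = omega, learning_rate = learning_rate,
                      epochs = epochs, standardize = standardize,
                      seed = seed, early_stop_patience = early_stop_patience)
  tr <- train_gatan(model, ds, val_ds, cfg)
  structure(list(model = tr$model, report = tr$report, scaling = tr$scaling,
                 encoding = enc, feature_names = ds$feature_names,
                 train_X = ds$X),
            class = "gatan_fit")
}

# softmax heads default to 2 outputs; regrow for K > 2 classes
resize_head <- function(head, K, seed) {
  if (nrow(head$W) == K) return(head)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  init_head_k(ncol(head$W), K, head$link)
}

init_head_k <- function(rep_dim, K, link) {
  s <- 1 / sqrt(rep_dim)
  task_head(matrix(stats::runif(K * rep_dim, -s, s), K, rep_dim),
            stats::runif(K, -s, s), link = link)
}

#' @export
print.gatan_fit <- function(x, ...) {
  cat("<gatan_fit> primary '", x$encoding$primary, "' (",
      x$encoding$primary_type, ")",
      if (length(x$encoding$aux))
        paste0(" + aux [", paste(x$encoding$aux, collapse = ", "), "]")
      else " (single task)",
      "; ", length(x$feature_names), " features\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object A `gatan_fit`.
#' @param new_data Data frame containing the feature columns used in
#'   training.
#' @param tasks `"primary"` (default) or `"all"` (adds one column per
#'   auxiliary task).
#' @param ... Unused.
#' @return A tibble with `.pred` (continuous), `.pred_prob`/`.pred_class`
#'   (binary/categorical); auxiliary predictions as `.pred_<name>`.
#' @export
predict.gatan_fit <- function(object, new_data, tasks = c("primary", "all"),
                              ...) {
  tasks <- match.arg(tasks)
  new_data <- as.data.frame(new_data)
  missing_cols <- setdiff(object$feature_names, names(new_data))
  if (length(missing_cols)) {
    stop("new_data lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(new_data[object$feature_names])
  pr <- predict_batch(object$model, X, object$scaling)
  enc <- object$encoding
  fmt <- function(pred, type, levels, prefix) {
    switch(type,
      continuous = stats::setNames(tibble::tibble(p = pred),
                                   paste0(prefix, "pred")),
      binary = stats::setNames(
        tibble::tibble(p = pred,
                       cl = levels[as.integer(pred >= 0.5) + 1L]),
        paste0(prefix, c("pred_prob", "pred_class"))),
      categorical = {
        out <- tibble::as_tibble(pred, .name_repair = "minimal")
        names(out) <- paste0(prefix, "prob_", levels)
        out[[paste0(prefix, "pred_class")]] <- levels[max.col(pred)]
        out
      })
  }
  res <- fmt(pr$primary, enc$primary_type, enc$levels[[enc$primary]], ".")
  if (tasks == "all") {
    for (k in seq_along(enc$aux)) {
      res <- dplyr::bind_cols(res, fmt(pr$aux[[k]], enc$aux_types[[k]],
                                       enc$levels[[enc$aux[k]]],
                                       paste0(".", enc$aux[k], "_")))
    }
  }
  res
}

#' Evaluate a fitted model on held-out data
#'
#' Computes the regression metric report (MSE, explained variance score,
#' median absolute error) of the primary-task predictions against the
#' observed primary target.
#'
#' @param fit A `gatan_fit` with a continuous primary target.
#' @param data Data frame containing the feature and primary target columns.
#' @return One-row tibble from [metric_report()].
#' @export
evaluate <- function(fit, data) {
  enc <- fit$encoding
  if (enc$primary_type != "continuous") {
    stop("evaluate: regression metrics need a continuous primary target",
         call. = FALSE)
  }
  pred <- predict(fit, data)$`.pred`
  metric_report(as.numeric(data[[enc$primary]]), pred)
}

# ---- broom-style methods ----------------------------------------------------

#' Tidy a fitted model: the feature-contribution ranking
#'
#' Returns the per-feature contribution shares toward the primary target
#' (specific branch, shared branch and their fusion-weighted combination),
#' sorted by combined contribution. See [rank_features()].
#'
#' @param x A `gatan_fit`.
#' @param reference Optional reference data (defaults to the training
#'   features stored in the fit) over which the fusion weights are averaged.
#' @param ... Unused.
#' @return Tibble with columns `feature`, `specific`, `shared`, `combined`,
#'   `rank`.
#' @export
tidy.gatan_fit <- function(x, reference = NULL, ...) {
  if (is.null(reference)) {
    # train_X is stored unstandardized; rank_features applies the scaling
    rank_features(x, x$train_X)
  } else {
    if (is.data.frame(reference)) {
      reference <- as.matrix(reference[x$feature_names])
    }
    rank_features(x, reference)
  }
}

#' Glance at a fitted model
#'
#' @param x A `gatan_fit`.
#' @param ... Unused.
#' @return One-row tibble: final training objective, epochs run, epoch
#'   selected, mean primary fusion weight a1, counts of features and
#'   auxiliary tasks.
#' @export
glance.gatan_fit <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    objective = if (length(r$objective)) r$objective[r$epoch_selected] else NA_real_,
    epochs_run = r$epochs_run,
    epoch_selected = r$epoch_selected,
    mean_a1 = r$mean_a1,
    n_features = length(x$feature_names),
    n_aux = length(x$encoding$aux),
    omega = r$config$omega
  )
}

# ---- plots ------------------------------------------------------------------

#' Plot the training trajectory of a fit
#'
#' Joint training objective (and primary validation loss, when available)
#' per epoch.
#'
#' @param object A `gatan_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gatan_fit <- function(object, ...) {
  r <- object$report
  df <- tibble::tibble(epoch = seq_along(r$objective),
                       value = r$objective, series = "training objective")
  if (length(r$val_loss)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      epoch = seq_along(r$val_loss), value = r$val_loss,
      series = "validation primary loss"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Bar chart of feature contributions
#'
#' The field's usual presentation of a contribution ranking: horizontal bars
#' of the combined contribution share for the top features.
#'
#' @param ranking Tibble from [rank_features()] / [tidy.gatan_fit()].
#' @param top_n Number of features to show (default 20).
#' @return A ggplot object.
#' @export
plot_contributions <- function(ranking, top_n = 20L) {
  df <- utils::head(dplyr::arrange(ranking, .data$rank), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$combined,
    y = stats::reorder(.data$feature, .data$combined))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "combined contribution share", y = NULL) +
    ggplot2::theme_minimal()
}
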