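# Independent oracles used across the suite.

# central finite-difference gradient of the joint objective; the step is
# near the cube root of machine epsilon, balancing truncation against
# round-off so both are ~1e-10 on objectives of magnitude ~1-10
fd_gradient <- function(model, data, omega = 1, delta = 1e-5) {
  theta <- flatten_params(model)
  vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + delta
    dn <- theta; dn[i] <- dn[i] - delta
    (joint_objective(unflatten_params(model, up), data, omega) -
     joint_objective(unflatten_params(model, dn), data, omega)) / (2 * delta)
  }, numeric(1L))
}

# worst-case relative error with an absolute floor for near-zero coordinates
max_rel_err <- function(g, fd, floor = 1e-4) {
  max(abs(g - fd) / pmax(abs(fd), floor))
}

# brute-force path enumeration of contribution shares, written independently
# of the package's matrix-chain implementation (own normalization code)
enum_contributions <- function(weight_mats, head_W) {
  shares <- lapply(weight_mats, function(W) {
    A <- abs(W)                     # fan_out x fan_in
    rs <- rowSums(A)
    S <- matrix(0, ncol(W), nrow(W))
    for (j in seq_len(nrow(W))) {
      S[, j] <- if (rs[j] == 0) 1 / ncol(W) else A[j, ] / rs[j]
    }
    S                               # fan_in x fan_out
  })
  hw <- colSums(abs(if (is.matrix(head_W)) head_W else rbind(head_W)))
  hcol <- if (sum(hw) == 0) rep(1 / length(hw), length(hw)) else hw / sum(hw)
  p <- nrow(shares[[1L]])
  out <- numeric(p)
  L <- length(shares)
  rec <- function(level, node, acc) {
    if (level > L) return(acc * hcol[node])
    total <- 0
    for (j in seq_len(ncol(shares[[level]]))) {
      total <- total + rec(level + 1L, j, acc * shares[[level]][node, j])
    }
    total
  }
  for (k in seq_len(p)) out[k] <- rec(1L, k, 1)
  out
}

# random small model + matching dataset for a given task configuration
rand_case <- function(seed, p = 3L, hidden = c(4L, 3L), n = 5L,
                      primary_type = "continuous",
                      aux_types = "continuous") {
  links <- vapply(c(primary_type, aux_types),
                  function(t) switch(t, continuous = "identity",
                                     binary = "sigmoid",
                                     categorical = "softmax"),
                  character(1L))
  model <- init_model(p, hidden, num_aux = length(aux_types),
                      task_links = links, seed = seed)
  set.seed(seed + 5000L)
  X <- matrix(rnorm(n * p), n, p)
  mk_target <- function(type) {
    switch(type,
      continuous = rnorm(n),
      binary = rbinom(n, 1L, 0.5),
      categorical = one_hot_oracle(sample(c("a", "b"), n, replace = TRUE),
                                   c("a", "b")))
  }
  ds <- gatan_dataset(X, mk_target(primary_type),
                      lapply(aux_types, mk_target),
                      primary_type = primary_type, aux_types = aux_types)
  list(model = model, data = ds)
}

one_hot_oracle <- function(x, levels) {
  Y <- matrix(0, length(x), length(levels))
  Y[cbind(seq_along(x), match(x, levels))] <- 1
  Y
}

# the synthetic multi-task study used by the benefit and recovery checks;
# memoised so the two acceptance properties share one set of fits
study_cache <- new.env(parent = emptyenv())

run_benefit_study <- function(seeds = 1:10) {
  key <- paste(seeds, collapse = "-")
  if (!is.null(study_cache[[key]])) return(study_cache[[key]])
  res <- lapply(seeds, function(seed) {
    sim <- simulate_multitask(n = 160, p = 30, k_informative = 5,
                              num_aux = 1, relatedness = 0.8, seed = seed)
    parts <- split_dataset(sim$data, c(100, 30, 30), seed = seed)
    st_cols <- setdiff(names(parts$train), "aux1")
    fit_mt <- gatan(parts$train, "y", "aux1", epochs = 4000,
                    learning_rate = 0.05, early_stop_patience = 300,
                    validation = parts$val, seed = seed)
    fit_st <- gatan(parts$train[st_cols], "y", epochs = 4000,
                    learning_rate = 0.05, early_stop_patience = 300,
                    validation = parts$val[st_cols], seed = seed)
    ranked <- rank_features(fit_mt, fit_mt$train_X)
    list(mse_mt = evaluate(fit_mt, parts$test)$mse,
         mse_st = evaluate(fit_st, parts$test)$mse,
         evs_st = evaluate(fit_st, parts$test)$evs,
         top5_hits = sum(ranked$feature[1:5] %in%
                           sprintf("x%02d", sim$truth$informative)))
  })
  out <- list(mse_mt = vapply(res, `[[`, numeric(1L), "mse_mt"),
              mse_st = vapply(res, `[[`, numeric(1L), "mse_st"),
              evs_st = vapply(res, `[[`, numeric(1L), "evs_st"),
              top5_hits = vapply(res, `[[`, numeric(1L), "top5_hits"))
  study_cache[[key]] <- out
  out
}

# independent recomputation of the validation loss used by early stopping
primary_val_loss_oracle <- function(model, val) {
  n <- nrow(val$X)
  tot <- 0
  for (i in seq_len(n)) {
    tot <- tot + (val$y_primary[i] - forward(model, val$X[i, ])$prediction_primary)^2
  }
  tot / n
}
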