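test_that("losses match their closed forms", {
  expect_equal(squared_loss(3, 3), 0)
  expect_equal(squared_loss(1, 3), 4)
  set.seed(1)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(squared_loss(a, b), squared_loss(b, a))

  eps <- 1e-12
  expect_equal(cross_entropy_loss(c(1, 0), c(1 - eps, eps)), 0,
               tolerance = 1e-9)
  expect_equal(cross_entropy_loss(c(1, 0), c(0.5, 0.5)), log(2),
               tolerance = 1e-12)
  expect_equal(cross_entropy_loss(c(0, 1), c(0.9, 0.1)), -log(0.1),
               tolerance = 1e-12)
  expect_error(cross_entropy_loss(c(1, 0), c(0.9, 0.4)), "probability")
})

test_that("the joint objective sums task losses with weight omega", {
  # constant-prediction model: zero weights, biases chosen by hand
  lay <- function(d_in) list(dense_layer(matrix(0, 1, d_in), 0))
  m <- structure(list(
    shared = subnetwork(lay(2), "shared"),
    primary = subnetwork(lay(2), "primary"),
    aux = list(subnetwork(lay(2), "auxiliary")),
    primary_head = task_head(0, 3, "identity"),   # always predicts 3
    aux_heads = list(task_head(0, 2, "identity")),# always predicts 2
    feature_names = c("a", "b"), hidden_dims = 1L), class = "gatan_model")
  ds <- gatan_dataset(matrix(0, 1, 2), 1, list(1))
  # primary squared error 4, aux squared error 1
  expect_equal(joint_objective(m, ds, omega = 1), 5)
  expect_equal(joint_objective(m, ds, omega = 0), 4)
  expect_equal(joint_objective(m, ds, omega = 2.5), 4 + 2.5)

  # perfect predictions give zero
  ds0 <- gatan_dataset(matrix(0, 3, 2), rep(3, 3), list(rep(2, 3)))
  expect_equal(joint_objective(m, ds0, omega = 1), 0)
})

test_that("joint objective is invariant to sample order and aux-task order", {
  cs <- rand_case(3, p = 4, n = 8, aux_types = c("continuous", "binary"))
  ds <- cs$data
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  ds_perm <- gatan_dataset(ds$X[perm, ], ds$y_primary[perm],
                           lapply(ds$y_aux, function(y) y[perm]),
                           aux_types = ds$aux_types)
  expect_equal(joint_objective(cs$model, ds, 1),
               joint_objective(cs$model, ds_perm, 1), tolerance = 1e-12)

  m_sw <- cs$model
  m_sw$aux <- m_sw$aux[2:1]; m_sw$aux_heads <- m_sw$aux_heads[2:1]
  ds_sw <- gatan_dataset(ds$X, ds$y_primary, ds$y_aux[2:1],
                         aux_types = ds$aux_types[2:1])
  expect_equal(joint_objective(cs$model, ds, 1),
               joint_objective(m_sw, ds_sw, 1), tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences across task mixes", {
  configs <- list(
    list(primary_type = "continuous", aux_types = "continuous"),
    list(primary_type = "continuous", aux_types = "binary"),
    list(primary_type = "categorical", aux_types = "continuous"),
    list(primary_type = "continuous", aux_types = c("continuous", "binary"))
  )
  for (i in seq_along(configs)) {
    for (seed in 1:3) {
      cs <- do.call(rand_case, c(list(seed = seed * 10 + i, p = 3,
                                      hidden = c(3, 2), n = 4), configs[[i]]))
      for (om in c(1, 0.3)) {
        g <- flatten_params(gatan_gradient(cs$model, cs$data, om))
        fd <- fd_gradient(cs$model, cs$data, om)
        expect_lt(max_rel_err(g, fd), 1e-5)
      }
    }
  }
})

test_that("omega = 0 zeroes all auxiliary gradients; zero residuals zero the head", {
  cs <- rand_case(5, p = 3, hidden = c(3, 2), n = 6)
  g0 <- gatan_gradient(cs$model, cs$data, omega = 0)
  expect_equal(max(abs(unlist(g0$aux))), 0)
  expect_equal(max(abs(unlist(g0$aux_heads))), 0)

  # dataset whose targets equal the model's own predictions: head gradient 0
  traces <- apply(cs$data$X, 1, function(x) forward(cs$model, x),
                  simplify = FALSE)
  y_hat <- vapply(traces, `[[`, numeric(1), "prediction_primary")
  a_hat <- vapply(traces, function(t) t$predictions_aux[[1]], numeric(1))
  ds0 <- gatan_dataset(cs$data$X, y_hat, list(a_hat))
  gz <- gatan_gradient(cs$model, ds0, omega = 1)
  expect_equal(max(abs(gz$primary_head$W)), 0, tolerance = 1e-12)
  expect_equal(max(abs(gz$aux_heads[[1]]$W)), 0, tolerance = 1e-12)
})

test_that("training descends, is deterministic, and epochs = 0 is a no-op", {
  cs <- rand_case(8, p = 3, hidden = c(4, 2), n = 20)
  cfg <- train_config(epochs = 50, learning_rate = 0.02, standardize = FALSE)
  tr <- train_gatan(cs$model, cs$data, cfg = cfg)
  expect_length(tr$report$objective, 50)
  expect_true(all(diff(tr$report$objective) <= 1e-10))
  expect_lt(tr$report$objective[50], joint_objective(cs$model, cs$data, 1))

  tr2 <- train_gatan(cs$model, cs$data, cfg = cfg)
  expect_identical(flatten_params(tr$model), flatten_params(tr2$model))

  tr0 <- train_gatan(cs$model, cs$data, cfg = train_config(epochs = 0))
  expect_identical(flatten_params(tr0$model), flatten_params(cs$model))
  expect_length(tr0$report$objective, 0)

  expect_error(train_gatan(cs$model, gatan_dataset(
    matrix(numeric(0), 0, 3), numeric(0), list(numeric(0)))), "empty")
})

test_that("with omega = 0 the primary-side trajectory equals the single-task one", {
  cs <- rand_case(13, p = 5, hidden = c(6, 3), n = 24)
  ds_st <- gatan_dataset(cs$data$X, cs$data$y_primary)
  m_st <- drop_aux(cs$model)
  primary_side <- function(m) flatten_params(drop_aux(m))
  for (ep in c(10, 40)) {
    cfg <- train_config(epochs = ep, learning_rate = 0.05, omega = 0)
    mt <- train_gatan(cs$model, cs$data, cfg = cfg)
    st <- train_gatan(m_st, ds_st, cfg = cfg)
    expect_equal(primary_side(mt$model), primary_side(st$model),
                 tolerance = 1e-12)
  }
})

test_that("early stopping returns the best-validation-epoch parameters", {
  cs <- rand_case(21, p = 3, hidden = c(4, 2), n = 30)
  val <- rand_case(22, p = 3, hidden = c(4, 2), n = 10)$data
  tr <- train_gatan(cs$model, cs$data, val,
                    train_config(epochs = 400, learning_rate = 0.2,
                                 early_stop_patience = 30,
                                 standardize = FALSE))
  r <- tr$report
  expect_equal(r$epoch_selected, which.min(r$val_loss))
  expect_lte(r$epochs_run, 400)
  expect_equal(primary_val_loss_oracle(tr$model, val), min(r$val_loss),
               tolerance = 1e-12)
})

test_that("predictions on the original scale are invariant to affine feature rescaling", {
  cs <- rand_case(31, p = 4, hidden = c(4, 2), n = 25)
  ds <- cs$data
  ds2 <- ds
  ds2$X[, 2] <- ds$X[, 2] * 1000 - 37   # rescale one input column
  cfg <- train_config(epochs = 60, learning_rate = 0.05, standardize = TRUE)
  t1 <- train_gatan(cs$model, ds, cfg = cfg)
  t2 <- train_gatan(cs$model, ds2, cfg = cfg)
  p1 <- gatan:::predict_batch(t1$model, ds$X, t1$scaling)$primary
  p2 <- gatan:::predict_batch(t2$model, ds2$X, t2$scaling)$primary
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("split_dataset partitions exactly, reproducibly, preserving the rows", {
  sim <- simulate_multitask(n = 194, p = 8, k_informative = 3, seed = 2)
  parts <- split_dataset(sim$dataset, c(134, 30, 30), seed = 9)
  expect_equal(nrow(parts$train$X), 134)
  expect_equal(nrow(parts$val$X), 30)
  expect_equal(nrow(parts$test$X), 30)
  recombined <- rbind(parts$train$X, parts$val$X, parts$test$X)
  expect_equal(sort(recombined[, 1]), sort(sim$dataset$X[, 1]))

  parts2 <- split_dataset(sim$dataset, c(134, 30, 30), seed = 9)
  expect_identical(parts$train$X, parts2$train$X)

  all_in <- split_dataset(sim$dataset, c(194, 0, 0), seed = 1)
  expect_equal(sort(all_in$train$y_primary), sort(sim$dataset$y_primary))
  expect_error(split_dataset(sim$dataset, c(194, 1, 0)), "sum")
})
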