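test_that("init_model builds branch shapes from hidden dims and is seeded", {
  m <- init_model(59, c(80, 40), num_aux = 1, seed = 7)
  expect_s3_class(m, "gatan_model")
  expect_length(forward(m, rep(0, 59))$h_s, 40)
  expect_equal(dim(m$shared$layers[[1]]$W), c(80, 59))
  expect_equal(dim(m$primary$layers[[2]]$W), c(40, 80))
  expect_length(m$aux, 1)
  expect_length(m$aux_heads, 1)

  # degenerate no-aux case
  m0 <- init_model(3, c(2), num_aux = 0, seed = 1)
  expect_length(m0$aux, 0)
  expect_length(m0$aux_heads, 0)

  # seeded determinism, bitwise
  expect_identical(flatten_params(init_model(5, c(6, 3), 1, seed = 7)),
                   flatten_params(init_model(5, c(6, 3), 1, seed = 7)))
  expect_error(init_model(0, c(4)), "positive")
})

test_that("primary-side initialization does not depend on the number of aux branches", {
  m0 <- init_model(6, c(5, 3), num_aux = 0, seed = 11)
  m2 <- init_model(6, c(5, 3), num_aux = 2, seed = 11)
  expect_identical(flatten_params(m0), flatten_params(drop_aux(m2)))
})

test_that("dense layer and subnetwork constructors enforce invariants", {
  expect_error(dense_layer(matrix(1, 2, 3), c(1)), "bias length")
  expect_error(dense_layer(matrix(c(1, NA), 1, 2), 0), "finite")
  l1 <- dense_layer(matrix(1, 4, 3), rep(0, 4))
  l2 <- dense_layer(matrix(1, 2, 5), rep(0, 2))  # fan_in 5 != fan_out 4
  expect_error(subnetwork(list(l1, l2)), "does not match")
})

test_that("forward_subnetwork applies affine-then-sigmoid per layer", {
  zero <- subnetwork(list(dense_layer(matrix(0, 3, 2), rep(0, 3))))
  expect_equal(forward_subnetwork(zero, c(5, -7)), rep(0.5, 3))
  eye <- subnetwork(list(dense_layer(diag(2), c(0, 0))))
  expect_equal(forward_subnetwork(eye, c(0, 0)), c(0.5, 0.5))
  one <- subnetwork(list(dense_layer(matrix(1, 1, 1), 0)))
  expect_equal(forward_subnetwork(one, 2), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_error(forward_subnetwork(one, c(1, 2)), "columns")
})

test_that("cosine similarity matches hand-computed values and handles zero norm", {
  v <- c(0.3, -1.2, 4)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "length")
})

test_that("fusion weights give the shared branch at least half, exactly convex", {
  expect_equal(fusion_weights(c(1, 2), c(1, 2)), c(w1 = 0.5, w2 = 0.5))
  expect_equal(fusion_weights(c(1, 0), c(0, 1)), c(w1 = 0, w2 = 1))
  w <- fusion_weights(c(1, 0), c(1, 1))
  expect_equal(unname(w[1]), 0.5 / sqrt(2), tolerance = 1e-12)
  expect_identical(unname(w[1] + w[2]), 1)
})

test_that("fuse is the convex combination of the two representations", {
  v <- c(0.2, 0.9, 0.4)
  expect_equal(fuse(v, v), v)
  expect_equal(fuse(c(1, 0), c(0, 1)), c(0, 1))
  w1 <- 0.5 / sqrt(2)
  expect_equal(fuse(c(1, 0), c(1, 1)),
               w1 * c(1, 0) + (1 - w1) * c(1, 1), tolerance = 1e-12)
})

test_that("task heads apply their link functions", {
  expect_equal(predict_head(task_head(c(1, 1), 0, "identity"), c(2, 3)), 5)
  expect_equal(predict_head(task_head(c(0, 0), 0, "sigmoid"), c(9, 9)), 0.5)
  sm <- task_head(matrix(0, 3, 2), rep(1, 3), "softmax")
  expect_equal(drop(predict_head(sm, c(0.4, 0.6))), rep(1 / 3, 3))
  expect_error(task_head(c(1, 1), 0, "probit"), "arg")
})

test_that("forward trace is internally consistent and matches a hand-chained oracle", {
  m <- init_model(4, c(3, 2), num_aux = 1, seed = 42)
  x <- c(0.5, -1, 2, 0.1)
  tr <- forward(m, x)
  expect_equal(tr$fused_primary,
               tr$fusion$a1 * tr$h_c + tr$fusion$a2 * tr$h_s,
               tolerance = 1e-14)

  # independent step-by-step evaluation outside the forward code path
  sg <- function(z) 1 / (1 + exp(-z))
  chain <- function(sub, x) {
    h <- x
    for (l in sub$layers) h <- sg(as.numeric(l$W %*% h + l$b))
    h
  }
  hs <- chain(m$shared, x)
  hc <- chain(m$primary, x)
  a1 <- sum(hc * hs) / (sqrt(sum(hc^2)) * sqrt(sum(hs^2))) / 2
  hfc <- a1 * hc + (1 - a1) * hs
  yhat <- sum(m$primary_head$W[1, ] * hfc) + m$primary_head$b
  expect_equal(tr$prediction_primary, yhat, tolerance = 1e-12)
  expect_equal(tr$fusion$a1, a1, tolerance = 1e-14)

  # identical branches force a1 = 0.5
  m$primary <- m$shared
  expect_equal(forward(m, x)$fusion$a1, 0.5, tolerance = 1e-14)

  # degenerate no-aux trace
  tr0 <- forward(init_model(4, c(3, 2), num_aux = 0, seed = 1), x)
  expect_length(tr0$h_a_list, 0)
  expect_length(tr0$predictions_aux, 0)
})

test_that("fusion and prediction invariants hold across random models and inputs", {
  for (seed in 1:40) {
    links <- if (seed %% 3 == 0) c("identity", "softmax") else c("identity", "identity")
    m <- init_model(4, c(5, 3), num_aux = 1, task_links = links, seed = seed)
    set.seed(seed)
    for (r in 1:5) {
      x <- rnorm(4, sd = 2)
      tr <- forward(m, x)
      a1 <- tr$fusion$a1
      expect_true(a1 > 0 && a1 <= 0.5)
      expect_identical(a1 + tr$fusion$a2, 1)
      b <- tr$fusion$b_pairs[[1]]
      expect_true(b[[1]] > 0 && b[[1]] <= 0.5)
      expect_identical(b[[1]] + b[[2]], 1)
      lo <- pmin(tr$h_c, tr$h_s); hi <- pmax(tr$h_c, tr$h_s)
      expect_true(all(tr$fused_primary >= lo - 1e-12) &&
                  all(tr$fused_primary <= hi + 1e-12))
      if (links[2] == "softmax") {
        expect_equal(sum(tr$predictions_aux[[1]]), 1, tolerance = 1e-12)
      }
      # determinism of the full trace
      expect_identical(tr, forward(m, x))
    }
  }
})
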