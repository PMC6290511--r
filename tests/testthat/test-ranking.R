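test_that("per-layer contribution shares normalize absolute weights per output", {
  C <- layer_contributions(dense_layer(matrix(c(2, 1, 1), 1, 3), 0))
  expect_equal(drop(C), c(0.5, 0.25, 0.25))
  C2 <- layer_contributions(dense_layer(matrix(1, 4, 3), rep(0, 4)))
  expect_true(all(abs(C2 - 1 / 3) < 1e-15))
  expect_equal(drop(layer_contributions(dense_layer(matrix(c(-2, 2), 1, 2), 0))),
               c(0.5, 0.5))
  # an all-zero weight row yields a uniform column, preserving conservation
  W <- rbind(c(0, 0), c(1, 3))
  Cz <- layer_contributions(dense_layer(W, c(0, 0)))
  expect_equal(Cz[, 1], c(0.5, 0.5))
  expect_equal(colSums(Cz), c(1, 1), tolerance = 1e-12)
})

test_that("propagated contributions respect symmetry and hand-computed cases", {
  # 2 inputs -> 3 hidden -> scalar head, all weights equal: full symmetry
  sub <- subnetwork(list(dense_layer(matrix(1, 3, 2), rep(0, 3))))
  head <- task_head(c(1, 1, 1), 0, "identity")
  expect_equal(propagate_contributions(sub, head), c(0.5, 0.5))

  # identity hidden layer: shares come straight from the head weights
  eye <- subnetwork(list(dense_layer(diag(2), c(0, 0))))
  expect_equal(propagate_contributions(eye, task_head(c(3, 1), 0, "identity")),
               c(0.75, 0.25))
  expect_error(propagate_contributions(sub, task_head(c(1, 1), 0, "identity")),
               "dimension")
})

test_that("matrix-chain propagation equals brute-force path enumeration", {
  set.seed(7)
  for (rep in 1:30) {
    n_layers <- sample(1:3, 1)          # plus the head: up to 4 weight stages
    dims <- c(sample(2:6, 1), sample(2:6, n_layers, replace = TRUE))
    layers <- lapply(seq_len(n_layers), function(t) {
      dense_layer(matrix(rnorm(dims[t + 1] * dims[t]), dims[t + 1], dims[t]),
                  rnorm(dims[t + 1]))
    })
    sub <- subnetwork(layers)
    multi <- rep %% 3 == 0
    hW <- if (multi) matrix(rnorm(3 * dims[n_layers + 1]), 3) else rnorm(dims[n_layers + 1])
    head <- task_head(hW, if (multi) rnorm(3) else 0,
                      if (multi) "softmax" else "identity")
    got <- propagate_contributions(sub, head)
    want <- enum_contributions(lapply(layers, `[[`, "W"), head$W)
    expect_equal(got, want, tolerance = 1e-10)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("contributions ignore weight signs and follow feature permutations", {
  set.seed(21)
  layers <- list(dense_layer(matrix(rnorm(12), 4, 3), rnorm(4)),
                 dense_layer(matrix(rnorm(8), 2, 4), rnorm(2)))
  sub <- subnetwork(layers)
  head <- task_head(rnorm(2), 0, "identity")
  base <- propagate_contributions(sub, head)

  flipped <- sub
  flipped$layers[[1]]$W[2, 3] <- -flipped$layers[[1]]$W[2, 3]
  expect_equal(propagate_contributions(flipped, head), base, tolerance = 1e-14)

  perm <- c(3, 1, 2)
  permuted <- sub
  permuted$layers[[1]]$W <- permuted$layers[[1]]$W[, perm]
  expect_equal(propagate_contributions(permuted, head), base[perm],
               tolerance = 1e-14)
})

test_that("rank_features combines branches with the averaged fusion weight", {
  m <- init_model(6, c(5, 3), num_aux = 1, seed = 3)
  set.seed(3)
  X <- matrix(rnorm(40 * 6), 40, 6)
  ranked <- rank_features(m, X)
  expect_named(ranked, c("feature", "specific", "shared", "combined", "rank"))
  expect_equal(sum(ranked$combined), 1, tolerance = 1e-9)
  expect_equal(ranked$rank, seq_len(6))
  expect_true(all(diff(ranked$combined) <= 1e-15))
  a1 <- attr(ranked, "a1")
  expect_true(a1 > 0 && a1 <= 0.5)
  expect_equal(ranked$combined,
               a1 * ranked$specific + (1 - a1) * ranked$shared,
               tolerance = 1e-12)

  # identical branches: combined equals the branch vector for any a1
  m$primary <- m$shared
  r2 <- rank_features(m, X)
  expect_equal(r2$combined, r2$specific, tolerance = 1e-12)
  expect_equal(r2$combined, r2$shared, tolerance = 1e-12)

  expect_error(rank_features(m, X[0, , drop = FALSE]), "nonempty")
})

test_that("auxiliary-task ranking mirrors the primary computation", {
  m <- init_model(5, c(4, 3), num_aux = 2, seed = 9)
  set.seed(9)
  X <- matrix(rnorm(30 * 5), 30, 5)
  r <- rank_features_aux(m, X, task = 2)
  expect_equal(sum(r$combined), 1, tolerance = 1e-9)
  expect_equal(r$specific,
               propagate_contributions(m$aux[[2]], m$aux_heads[[2]])[
                 match(r$feature, m$feature_names)],
               tolerance = 1e-12)
})
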