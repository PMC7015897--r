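test_that("input encoding centers, scales and guards constant markers", {
  g <- simulate_genotypes(40, 12, seed = 1)
  d <- g$dosages
  d[, 3] <- 2                                  # constant marker
  g <- geno_matrix(d, 2)
  X <- encode_input(g)
  expect_equal(dim(X), c(40, 12))
  expect_true(all(abs(colMeans(X)) < 1e-10))
  expect_equal(unname(X[, 3]), rep(0, 40))     # zero column, no Inf
  # tetraploid vs diploidized coding of one panel encode differently
  g4 <- simulate_genotypes(30, 10, ploidy = 4, seed = 2)
  expect_false(isTRUE(all.equal(encode_input(g4),
                                encode_input(diploidize(g4)),
                                check.attributes = FALSE)))
  gm <- geno_matrix(matrix(c(0, NA, 2), ncol = 1), 2)
  expect_error(encode_input(gm), "missing")
})

test_that("architecture construction follows the fixed topology", {
  pt <- fast_point(n_filters = 16, dense_neurons = 4, hidden_layers = 1)
  arch <- build_cnn(pt, p = 300, seed = 1)
  expect_equal(arch$layers,
               c("conv1d(filters=16, width=3, stride=1, activation=relu)",
                 "maxpool(width=3)", "flatten",
                 "dense(4, activation=relu)", "dense(1, activation=linear)"))
  expect_equal(arch$Tconv, 298)
  expect_equal(arch$Tpool, 99)
  # deterministic parameter count: conv 3*16+16, dense (99*16)*4+4, out 4+1
  expect_equal(arch$n_params, 3 * 16 + 16 + 99 * 16 * 4 + 4 + 4 + 1)
  # parameter count increases with filters
  counts <- vapply(c(16, 32, 64, 128), function(f) {
    build_cnn(fast_point(n_filters = f), 300, seed = 1)$n_params
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
  # same point and seed give identical initial weights
  a1 <- build_cnn(pt, 300, seed = 9)
  a2 <- build_cnn(pt, 300, seed = 9)
  expect_identical(a1$W_conv, a2$W_conv)
  expect_identical(a1$dense, a2$dense)
  expect_error(build_cnn(pt, p = 4), "p too small")
})

test_that("conv/pool primitives match direct evaluation", {
  set.seed(5)
  X <- matrix(rnorm(4 * 10), 4, 10)
  W <- matrix(rnorm(6), 3, 2)
  b <- c(0.5, -1)
  Z <- conv1d_forward_cpp(X, W, b)
  for (i in 1:4) for (t in 1:8) for (f in 1:2) {
    expect_equal(Z[i, t, f], sum(W[, f] * X[i, t:(t + 2)]) + b[f])
  }
  mp <- maxpool_forward_cpp(Z, 3L)
  expect_equal(dim(mp$out), c(4, 2, 2))
  for (i in 1:4) for (t2 in 1:2) for (f in 1:2) {
    expect_equal(mp$out[i, t2, f], max(Z[i, (3 * t2 - 2):(3 * t2), f]))
  }
})

test_that("training gradients descend: a linear trait is learned", {
  set.seed(9)
  g <- simulate_genotypes(120, 30, seed = 3)
  X <- encode_input(g)
  y <- 2 * X[, 5] + rnorm(120, 0, 0.1)
  arch <- build_cnn(fast_point(), 30, seed = 1)
  pred <- train_predict_cnn(arch, X, y, X, epochs = 100, batch = 16, seed = 2)
  expect_gt(cor(as.vector(pred), y), 0.95)
  expect_false(attr(pred, "diverged"))
})

test_that("zero epochs predicts from initial weights and stays finite", {
  set.seed(10)
  X <- matrix(rnorm(20 * 15), 20, 15)
  arch <- build_cnn(fast_point(), 15, seed = 4)
  y <- rnorm(20)
  pred <- train_predict_cnn(arch, X, y, X, epochs = 0, seed = 4)
  expect_equal(attr(pred, "epochs_used"), 0)
  expect_true(all(is.finite(pred)))
  # and equals a raw forward pass of the untouched architecture, mapped back
  # from the standardized-response scale
  expect_equal(as.vector(pred),
               polyGP:::cnn_forward(arch, X)$pred * sd(y) + mean(y))
})

test_that("predictions are sensitive to marker order (convolution is local)", {
  set.seed(11)
  g <- simulate_genotypes(60, 40, seed = 12)
  X <- encode_input(g)
  y <- rowSums(X[, 1:3]) + rnorm(60, 0, 0.2)
  arch <- build_cnn(fast_point(), 40, seed = 5)
  pred <- train_predict_cnn(arch, X, y, X, epochs = 30, batch = 16, seed = 6)
  perm <- sample(40)
  arch2 <- build_cnn(fast_point(), 40, seed = 5)
  pred2 <- train_predict_cnn(arch2, X[, perm], y, X[, perm],
                             epochs = 30, batch = 16, seed = 6)
  expect_false(isTRUE(all.equal(as.vector(pred), as.vector(pred2))))
})

test_that("random search is reproducible and decoupled from evaluation", {
  set.seed(13)
  g <- simulate_genotypes(60, 20, seed = 14)
  X <- encode_input(g)
  y <- X[, 4] + rnorm(60, 0, 0.5)
  tiny_grid <- list(
    activation = c("relu", "linear"), n_filters = 16,
    weight_decay_conv = 0, weight_decay_dense = 0,
    learning_rate = c(0.01, 0.0025), dense_neurons = 4, hidden_layers = 1,
    dropout_conv = 0, dropout_dense = c(0, 0.1)
  )
  s1 <- search_hyperparams(X, y, budget = 8, epochs = 5, seed = 7,
                           grid = tiny_grid)
  expect_equal(nrow(s1), 8)                     # exhaustive: budget = grid size
  expect_equal(nrow(dplyr::distinct(s1[names(tiny_grid)])), 8)
  s2 <- search_hyperparams(X, y, budget = 8, epochs = 5, seed = 7,
                           grid = tiny_grid)
  expect_equal(s1$accuracy, s2$accuracy)
  expect_equal(attr(s1, "best_point"), attr(s2, "best_point"))
  expect_equal(attr(s1, "best_accuracy"), max(s1$accuracy, na.rm = TRUE))
  # accuracies vary across points: the point matters
  expect_gt(sd(s1$accuracy, na.rm = TRUE), 0)
  # doubling the inner validation fraction cannot change which points are drawn
  s3 <- search_hyperparams(X, y, budget = 4, inner_frac = 0.2, epochs = 1,
                           seed = 7, grid = tiny_grid)
  s4 <- search_hyperparams(X, y, budget = 4, inner_frac = 0.4, epochs = 1,
                           seed = 7, grid = tiny_grid)
  expect_equal(as.data.frame(s3)[names(tiny_grid)],
               as.data.frame(s4)[names(tiny_grid)])
  expect_error(search_hyperparams(X, y, budget = 9, grid = tiny_grid),
               "budget exceeds")
})

test_that("diverging configurations are flagged, not fatal", {
  set.seed(15)
  X <- matrix(rnorm(60 * 10, 0, 50), 60, 10)
  y <- rnorm(60)
  # absurd learning rate overflows the deep linear stack into NaN
  arch <- build_cnn(fast_point(learning_rate = 1e30, activation = "linear",
                               hidden_layers = 10, dense_neurons = 16),
                    10, seed = 8)
  pred <- train_predict_cnn(arch, X, y, X, epochs = 30, batch = 16, seed = 8)
  expect_true(attr(pred, "diverged"))
  expect_true(all(is.na(pred)))
})
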