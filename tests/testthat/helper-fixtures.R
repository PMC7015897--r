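# small panels shared across tests; everything generated in code

tiny_diploid <- function() {
  # one marker with p = 0.5, dosages 0/1/2 -- the hand-worked kernel example
  geno_matrix(matrix(c(0, 1, 2), ncol = 1), ploidy = 2)
}

random_panel <- function(n = 6, p = 5, ploidy = 2, seed = 42) {
  simulate_genotypes(n, p, ploidy, maf_range = c(0.2, 0.5),
                     ld_block_size = 1, seed = seed)
}

# loop-based direct evaluation of the printed A / D(diploid) / E formulas
brute_A <- function(g) {
  d <- g$dosages
  pj <- colMeans(d) / g$ploidy
  Z <- matrix(0, nrow(d), ncol(d))
  for (i in seq_len(nrow(d))) for (j in seq_len(ncol(d))) {
    Z[i, j] <- d[i, j] - g$ploidy * pj[j]
  }
  denom <- 0
  for (j in seq_len(ncol(d))) denom <- denom + g$ploidy * pj[j] * (1 - pj[j])
  out <- matrix(0, nrow(d), nrow(d))
  for (i in seq_len(nrow(d))) for (k in seq_len(nrow(d))) {
    out[i, k] <- sum(Z[i, ] * Z[k, ]) / denom
  }
  out
}

brute_D_diploid <- function(g) {
  d <- g$dosages
  pj <- colMeans(d) / 2
  M <- matrix(0, nrow(d), ncol(d))
  for (i in seq_len(nrow(d))) for (j in seq_len(ncol(d))) {
    M[i, j] <- switch(d[i, j] + 1,
                      -2 * pj[j]^2,
                      2 * pj[j] * (1 - pj[j]),
                      -2 * (1 - pj[j])^2)
  }
  denom <- 0
  for (j in seq_len(ncol(d))) denom <- denom + (pj[j] * (1 - pj[j]))^2
  denom <- 4 * denom
  out <- matrix(0, nrow(d), nrow(d))
  for (i in seq_len(nrow(d))) for (k in seq_len(nrow(d))) {
    out[i, k] <- sum(M[i, ] * M[k, ]) / denom
  }
  out
}

# a random search table drawn from the real menus, with a pluggable
# accuracy-generating function
fake_search_table <- function(n = 80, seed = 1, accuracy_fn = NULL) {
  set.seed(seed)
  grid <- cnn_hyper_grid()
  tab <- tibble::as_tibble(lapply(grid, sample, size = n, replace = TRUE))
  tab$accuracy <- if (is.null(accuracy_fn)) {
    runif(n)
  } else {
    accuracy_fn(tab)
  }
  tab
}

# a tiny hyperparameter point that trains fast
fast_point <- function(...) {
  utils::modifyList(
    list(activation = "relu", n_filters = 16, weight_decay_conv = 0,
         weight_decay_dense = 0, learning_rate = 0.01, dense_neurons = 4,
         hidden_layers = 1, dropout_conv = 0, dropout_dense = 0),
    list(...)
  )
}
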