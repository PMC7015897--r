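#' Hyperparameter menus for the CNN random search
#'
#' The searchable space: activation (relu, tanh, linear), number of
#' convolution filters (16, 32, 64, 128), weight decay per layer
#' (0, 0.1, 0.01, 0.001), learning rate (0.1, 0.01, 0.001, 0.0025), dense
#' neurons (4, 8, 12, 16), hidden dense layers (1, 5, 10) and dropout per
#' layer (0, 0.01, 0.1, 0.2).  Decay and dropout are exposed separately for
#' the convolution block and the dense block.
#'
#' @return named list of menu vectors.
#' @export
cnn_hyper_grid <- function() {
  list(
    activation = c("relu", "tanh", "linear"),
    n_filters = c(16, 32, 64, 128),
    weight_decay_conv = c(0, 0.1, 0.01, 0.001),
    weight_decay_dense = c(0, 0.1, 0.01, 0.001),
    learning_rate = c(0.1, 0.01, 0.001, 0.0025),
    dense_neurons = c(4, 8, 12, 16),
    hidden_layers = c(1, 5, 10),
    dropout_conv = c(0, 0.01, 0.1, 0.2),
    dropout_dense = c(0, 0.01, 0.1, 0.2)
  )
}

grid_size <- function(grid = cnn_hyper_grid()) prod(lengths(grid))

# decode a 1-based linear index into a hyperparameter point (mixed radix)
decode_point <- function(index, grid = cnn_hyper_grid()) {
  sizes <- lengths(grid)
  idx <- index - 1
  point <- vector("list", length(grid))
  names(point) <- names(grid)
  for (k in seq_along(grid)) {
    point[[k]] <- grid[[k]][idx %% sizes[k] + 1]
    idx <- idx %/% sizes[k]
  }
  point
}

#' Encode a genotype panel as CNN input
#'
#' Per-marker centered and unit-scaled dosages, marker order preserved, one
#' implicit channel.  Constant markers become zero columns (scale divisor is
#' `max(sd, 1e-8)`).
#'
#' @param genotypes a [geno_matrix()] with no missing entries.
#' @return numeric matrix (individuals x markers) with attribute
#'   `center`/`scale` so validation panels can reuse the training encoding.
#' @export
encode_input <- function(genotypes) {
  d <- genotypes$dosages
  if (anyNA(d)) stop("missing dosages; impute first", call. = FALSE)
  ctr <- colMeans(d)
  scl <- pmax(apply(d, 2, sd), 1e-8)
  X <- sweep(sweep(d, 2, ctr), 2, scl, `/`)
  attr(X, "center") <- ctr
  attr(X, "scale") <- scl
  X
}

#' Build a CNN architecture from a hyperparameter point
#'
#' The fixed topology: one convolution block (kernel width 3, stride 1,
#' `n_filters` filters, chosen activation, optional dropout), max-pooling of
#' width 3, flatten, `hidden_layers` dense layers of `dense_neurons` neurons
#' (same activation, optional dropout), and a final linear dense layer of
#' size 1.  Weights are initialized from seeded scaled normals
#' (`sd = sqrt(2 / fan_in)`), so two builds from the same point and seed are
#' identical.
#'
#' @param point a hyperparameter point (named list as from
#'   [cnn_hyper_grid()] menus).
#' @param p number of markers (>= 5 so one pooling window exists).
#' @param seed integer seed for weight initialization.
#' @return a `cnn_arch` object: layer metadata, parameter count `n_params`,
#'   and the initial weights.
#' @export
build_cnn <- function(point, p, seed = 1) {
  kernel_width <- 3L
  pool_width <- 3L
  Tconv <- p - kernel_width + 1L
  if (p < kernel_width || Tconv < pool_width) {
    stop("p too small for convolution + pooling (need p >= 5)", call. = FALSE)
  }
  Tpool <- Tconv %/% pool_width
  F <- as.integer(point$n_filters)
  m <- as.integer(point$dense_neurons)
  H <- as.integer(point$hidden_layers)
  flat <- Tpool * F
  set.seed(seed)
  W_conv <- matrix(rnorm(kernel_width * F, 0, sqrt(2 / kernel_width)),
                   kernel_width, F)
  b_conv <- numeric(F)
  dims <- c(flat, rep(m, H), 1L)
  dense <- vector("list", H + 1)
  for (l in seq_len(H + 1)) {
    fan_in <- dims[l]
    dense[[l]] <- list(
      W = matrix(rnorm(fan_in * dims[l + 1], 0, sqrt(2 / fan_in)),
                 fan_in, dims[l + 1]),
      b = numeric(dims[l + 1])
    )
  }
  n_params <- length(W_conv) + F + sum(vapply(dense, function(d) {
    length(d$W) + length(d$b)
  }, numeric(1)))
  layers <- c(
    sprintf("conv1d(filters=%d, width=%d, stride=1, activation=%s)",
            F, kernel_width, point$activation),
    sprintf("maxpool(width=%d)", pool_width),
    if (point$dropout_conv > 0) sprintf("dropout(%.2f)", point$dropout_conv),
    "flatten",
    rep(sprintf("dense(%d, activation=%s)", m, point$activation), H),
    "dense(1, activation=linear)"
  )
  structure(list(point = point, p = as.integer(p), kernel_width = kernel_width,
                 pool_width = pool_width, Tconv = Tconv, Tpool = Tpool,
                 layers = layers, n_params = n_params, seed = seed,
                 W_conv = W_conv, b_conv = b_conv, dense = dense),
            class = "cnn_arch")
}

#' @export
print.cnn_arch <- function(x, ...) {
  cat(sprintf("<cnn_arch> input p = %d, %d parameters\n", x$p, x$n_params))
  cat(paste0("  ", x$layers, collapse = "\n"), "\n")
  invisible(x)
}

activate <- function(z, kind) {
  switch(kind, relu = pmax(z, 0), tanh = tanh(z), linear = z)
}
activate_grad <- function(a, kind) {
  # derivative expressed through the activation value
  switch(kind, relu = (a > 0) * 1, tanh = 1 - a^2, linear = array(1, dim(a) %||% length(a)))
}

cnn_forward <- function(arch, X, training = FALSE) {
  pt <- arch$point
  Z <- conv1d_forward_cpp(X, arch$W_conv, arch$b_conv)
  A <- activate(Z, pt$activation)
  dim(A) <- dim(Z)
  mp <- maxpool_forward_cpp(A, arch$pool_width)
  P <- mp$out
  mask_conv <- NULL
  if (training && pt$dropout_conv > 0) {
    mask_conv <- (runif(length(P)) >= pt$dropout_conv) / (1 - pt$dropout_conv)
    P <- P * mask_conv
  }
  Fl <- matrix(P, nrow = nrow(X))      # (B, Tpool * F); batch is dim 1
  acts <- list(Fl)                     # layer inputs (post-dropout)
  raw <- vector("list", length(arch$dense) - 1)  # activations pre-dropout
  masks <- vector("list", length(arch$dense))
  H <- length(arch$dense) - 1
  cur <- Fl
  for (l in seq_len(H)) {
    a <- activate(sweep(cur %*% arch$dense[[l]]$W, 2, arch$dense[[l]]$b, `+`),
                  pt$activation)
    raw[[l]] <- a
    if (training && pt$dropout_dense > 0) {
      masks[[l]] <- matrix((runif(length(a)) >= pt$dropout_dense) /
                             (1 - pt$dropout_dense), nrow(a))
      a <- a * masks[[l]]
    }
    cur <- a
    acts[[l + 1]] <- cur
  }
  out <- drop(sweep(cur %*% arch$dense[[H + 1]]$W, 2, arch$dense[[H + 1]]$b, `+`))
  list(pred = out, conv_act = A, argmax = mp$argmax, mask_conv = mask_conv,
       acts = acts, raw = raw, masks = masks)
}

cnn_backward <- function(arch, X, fwd, dpred) {
  pt <- arch$point
  H <- length(arch$dense) - 1
  grads <- vector("list", H + 1)
  delta <- matrix(dpred, ncol = 1)
  for (l in rev(seq_len(H + 1))) {
    a_prev <- fwd$acts[[l]]
    grads[[l]] <- list(dW = crossprod(a_prev, delta), db = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(arch$dense[[l]]$W)
      if (!is.null(fwd$masks[[l - 1]])) delta <- delta * fwd$masks[[l - 1]]
      delta <- delta * activate_grad(fwd$raw[[l - 1]], pt$activation)
    }
  }
  dFl <- delta %*% t(arch$dense[[1]]$W)
  if (!is.null(fwd$mask_conv)) dFl <- as.vector(dFl) * fwd$mask_conv
  dP <- array(dFl, dim = c(nrow(X), arch$Tpool, ncol(arch$W_conv)))
  dA <- maxpool_backward_cpp(dP, fwd$argmax, arch$Tconv)
  dZ <- dA * activate_grad(fwd$conv_act, pt$activation)
  dim(dZ) <- dim(fwd$conv_act)
  cg <- conv1d_backward_cpp(X, arch$W_conv, dZ)
  list(dense = grads, dW_conv = cg$dW, db_conv = cg$db)
}

#' Train a CNN and predict a validation panel
#'
#' Minibatch training on the mean-squared-error objective with the Adam
#' optimizer at the point's learning rate and per-layer L2 weight decay
#' (added to the gradient).  Adam's per-parameter step normalization is what
#' makes the whole learning-rate menu usable: with plain gradient descent the
#' flatten layer's large fan-in caps the stable step size far below the
#' menu's values and most configurations explode.  Optionally monitors a
#' held-out set for early stopping (patience in epochs, restoring the best
#' weights).  A run whose loss becomes non-finite is flagged as diverged and
#' returns `NA` predictions so a surrounding search can continue.
#'
#' @param arch a [build_cnn()] architecture.
#' @param X_train,y_train encoded training inputs / phenotypes.
#' @param X_valid encoded panel to predict (rows to score).
#' @param epochs training epochs (default 50).
#' @param batch minibatch size (default 32).
#' @param seed seed for shuffling, dropout and (re)initialization.
#' @param monitor optional `list(X =, y =)` held-out set for early stopping.
#' @param patience early-stopping patience in epochs.
#' @return numeric predictions for `X_valid`, with attributes
#'   `epochs_used` and `diverged`.
#' @export
train_predict_cnn <- function(arch, X_train, y_train, X_valid,
                              epochs = 50, batch = 32, seed = 1,
                              monitor = NULL, patience = 10) {
  stopifnot(inherits(arch, "cnn_arch"), ncol(X_train) == arch$p)
  pt <- arch$point
  lr <- pt$learning_rate
  # train on the standardized response so the learning-rate menu is on a
  # scale-free footing; predictions are mapped back afterwards
  y_center <- mean(y_train)
  y_scale <- max(sd(y_train), 1e-8)
  y_train <- (y_train - y_center) / y_scale
  if (!is.null(monitor)) monitor$y <- (monitor$y - y_center) / y_scale
  set.seed(seed)
  n <- nrow(X_train)
  best <- NULL
  best_loss <- Inf
  wait <- 0
  diverged <- FALSE
  epochs_used <- 0
  adam <- adam_state(arch)
  if (epochs > 0) {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1, n)]
        Xb <- X_train[idx, , drop = FALSE]
        fwd <- cnn_forward(arch, Xb, training = TRUE)
        resid <- fwd$pred - y_train[idx]
        if (any(!is.finite(resid))) { diverged <- TRUE; break }
        dpred <- 2 * resid / length(idx)
        gr <- cnn_backward(arch, Xb, fwd, dpred)
        upd <- adam_update(adam, arch, gr, pt, lr)
        adam <- upd$state
        arch <- upd$arch
        if (any(!is.finite(arch$W_conv))) { diverged <- TRUE; break }
      }
      epochs_used <- ep
      if (diverged) break
      if (!is.null(monitor)) {
        mp <- cnn_forward(arch, monitor$X)$pred
        mloss <- mean((mp - monitor$y)^2)
        if (!is.finite(mloss)) { diverged <- TRUE; break }
        if (mloss < best_loss - 1e-12) {
          best_loss <- mloss
          best <- arch
          wait <- 0
        } else {
          wait <- wait + 1
          if (wait >= patience) break
        }
      }
    }
  }
  if (diverged) {
    out <- rep(NA_real_, nrow(X_valid))
  } else {
    if (!is.null(best)) arch <- best
    out <- cnn_forward(arch, X_valid)$pred * y_scale + y_center
  }
  attr(out, "epochs_used") <- epochs_used
  attr(out, "diverged") <- diverged
  out
}

# Adam optimizer bookkeeping (beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
adam_state <- function(arch) {
  zero_like <- function(x) x * 0
  list(t = 0,
       m = list(Wc = zero_like(arch$W_conv), bc = zero_like(arch$b_conv),
                dense = lapply(arch$dense, function(d) {
                  list(W = zero_like(d$W), b = zero_like(d$b))
                })),
       v = list(Wc = zero_like(arch$W_conv), bc = zero_like(arch$b_conv),
                dense = lapply(arch$dense, function(d) {
                  list(W = zero_like(d$W), b = zero_like(d$b))
                })))
}

adam_update <- function(state, arch, gr, pt, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- function(m, v, g) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    list(m = m, v = v, delta = lr * (m / bc1) / (sqrt(v / bc2) + eps))
  }
  s <- step(state$m$Wc, state$v$Wc,
            gr$dW_conv + pt$weight_decay_conv * arch$W_conv)
  state$m$Wc <- s$m; state$v$Wc <- s$v
  arch$W_conv <- arch$W_conv - s$delta
  s <- step(state$m$bc, state$v$bc, gr$db_conv)
  state$m$bc <- s$m; state$v$bc <- s$v
  arch$b_conv <- arch$b_conv - s$delta
  for (l in seq_along(arch$dense)) {
    s <- step(state$m$dense[[l]]$W, state$v$dense[[l]]$W,
              gr$dense[[l]]$dW + pt$weight_decay_dense * arch$dense[[l]]$W)
    state$m$dense[[l]]$W <- s$m; state$v$dense[[l]]$W <- s$v
    arch$dense[[l]]$W <- arch$dense[[l]]$W - s$delta
    s <- step(state$m$dense[[l]]$b, state$v$dense[[l]]$b, gr$dense[[l]]$db)
    state$m$dense[[l]]$b <- s$m; state$v$dense[[l]]$b <- s$v
    arch$dense[[l]]$b <- arch$dense[[l]]$b - s$delta
  }
  list(state = state, arch = arch)
}
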