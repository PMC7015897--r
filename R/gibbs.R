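#' Gibbs sampler configuration
#'
#' Chain settings and prior hyperparameters shared by all Bayesian fitters.
#' Variance components have scaled-inverse-chi-square priors with `prior_df`
#' degrees of freedom; prior scales are set so the prior mode of each
#' component matches `prior_R2` of the phenotypic variance (split equally
#' across components in multi-component models), the remainder going to the
#' residual.
#'
#' @param n_iter total Gibbs cycles (default 6000).
#' @param burn_in cycles discarded (default 1000).
#' @param thin keep every `thin`-th retained cycle.
#' @param seed integer seed; chains are bitwise reproducible given it.
#' @param prior_df prior degrees of freedom for every variance component.
#' @param prior_R2 prior fraction of phenotypic variance attributed to the
#'   genetic term(s).
#' @param fixed_variances optional `list(sigma2_b =, sigma2_e =)`; when given,
#'   variance updates are skipped and the sampler runs at these values
#'   (useful for closed-form cross-checks).
#' @return a `gibbs_config` list.
#' @export
gibbs_config <- function(n_iter = 6000, burn_in = 1000, thin = 1, seed = 1,
                         prior_df = 5, prior_R2 = 0.5, fixed_variances = NULL) {
  stopifnot(burn_in < n_iter, thin >= 1, prior_df > 0,
            prior_R2 > 0, prior_R2 < 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_df = prior_df, prior_R2 = prior_R2,
                 fixed_variances = fixed_variances),
            class = "gibbs_config")
}

check_xy <- function(X, y) {
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X))) stop("X contains missing/non-finite values", call. = FALSE)
  if (anyNA(y)) stop("missing phenotypes not supported; subset first", call. = FALSE)
  if (var(y) <= 0) stop("constant phenotype; degenerate response", call. = FALSE)
  invisible(TRUE)
}

new_gp_fit <- function(model, intercept, effects, variance_samples,
                       training_ids, config, extra = list()) {
  structure(c(list(model = model, intercept_mean = intercept,
                   effect_means = effects,
                   variance_samples = variance_samples,
                   training_ids = training_ids, config = config), extra),
            class = "gp_fit")
}

#' Bayesian ridge regression (BRR) on a marker design
#'
#' Whole-genome regression `y = mu + X beta + e` with a common normal prior
#' `beta_j ~ N(0, sigma2_b)`, sampled marker-by-marker by Gibbs.  Both
#' variances have scaled-inverse-chi-square priors (see [gibbs_config()]).
#'
#' @param X numeric matrix (individuals x predictors), typically
#'   [additive_design()] or [dosage_dummy_matrix()] output.
#' @param y numeric phenotype vector aligned to rows of `X`.
#' @param config a [gibbs_config()].
#' @return a `gp_fit` with posterior-mean intercept and effects and retained
#'   draws of `sigma2_b` and `sigma2_e`.
#' @export
fit_brr <- function(X, y, config = gibbs_config()) {
  X <- as.matrix(X)
  check_xy(X, y)
  vy <- var(y)
  msx <- sum(colMeans(X^2) - colMeans(X)^2)
  if (msx <= 0) msx <- sum(colMeans(X^2))
  df <- config$prior_df
  r2 <- config$prior_R2
  fixed <- !is.null(config$fixed_variances)
  if (fixed) {
    init_s2b <- config$fixed_variances$sigma2_b
    init_s2e <- config$fixed_variances$sigma2_e
    ss_b <- ss_e <- 0
  } else {
    init_s2b <- r2 * vy / msx
    init_s2e <- (1 - r2) * vy
    ss_b <- init_s2b * (df + 2)
    ss_e <- init_s2e * (df + 2)
  }
  set.seed(config$seed)
  out <- brr_gibbs_cpp(X, y, config$n_iter, config$burn_in, config$thin,
                       df, ss_b, ss_e, init_s2b, init_s2e, fixed)
  eff <- drop(out$beta)
  names(eff) <- colnames(X)
  new_gp_fit("BRR", out$mu, eff,
             list(sigma2_b = out$s2b, sigma2_e = out$s2e),
             rownames(X), config)
}

#' Bayesian lasso (BL) on a marker design
#'
#' Same linear model as [fit_brr()] but with a Laplace (double-exponential)
#' prior on effects, implemented as the standard scale-mixture of normals with
#' exponential mixing (Park & Casella): `beta_j ~ N(0, sigma2_e tau2_j)`,
#' `tau2_j ~ Exp(lambda^2 / 2)`, and a gamma hyperprior on `lambda^2`.
#' The Laplace prior shrinks but never zeroes effects — this is not variable
#' selection.
#'
#' @inheritParams fit_brr
#' @return a `gp_fit` with draws of `sigma2_e` and `lambda2`.
#' @export
fit_bl <- function(X, y, config = gibbs_config()) {
  X <- as.matrix(X)
  check_xy(X, y)
  vy <- var(y)
  msx <- sum(colMeans(X^2) - colMeans(X)^2)
  if (msx <= 0) msx <- sum(colMeans(X^2))
  df <- config$prior_df
  r2 <- config$prior_R2
  ss_e <- (1 - r2) * vy * (df + 2)
  init_s2e <- (1 - r2) * vy
  init_lambda2 <- 2 * (1 - r2) / r2 * msx
  lambda2_shape <- 1.1
  lambda2_rate <- (lambda2_shape - 1) / init_lambda2
  set.seed(config$seed)
  out <- bl_gibbs_cpp(X, y, config$n_iter, config$burn_in, config$thin,
                      df, ss_e, lambda2_shape, lambda2_rate,
                      init_s2e, init_lambda2)
  eff <- drop(out$beta)
  names(eff) <- colnames(X)
  new_gp_fit("BL", out$mu, eff,
             list(sigma2_e = out$s2e, lambda2 = out$lambda2),
             rownames(X), config)
}

#' BRR on the dosage-class dummy design (BRR-GM)
#'
#' Builds the centered/scaled per-dosage-class indicator matrix Omega via
#' [dosage_dummy_matrix()] and fits [fit_brr()] on it, so each dosage class
#' of each marker gets its own effect; this "general model" can absorb
#' arbitrary within-locus (dominance-like) genotype effects.
#'
#' @param genotypes a [geno_matrix()] of the training individuals (no missing
#'   entries).
#' @inheritParams fit_brr
#' @return a `gp_fit` of model `"BRR-GM"` whose effect names are
#'   `"<marker>.<class>"` columns.
#' @export
fit_brr_gm <- function(genotypes, y, config = gibbs_config()) {
  X <- dosage_dummy_matrix(genotypes)
  fit <- fit_brr(X, y, config)
  fit$model <- "BRR-GM"
  fit
}

eigen_basis <- function(K, tol = 1e-8) {
  eg <- eigen(unclass(K), symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values)
  list(U = eg$vectors[, keep, drop = FALSE], d = eg$values[keep])
}

#' RKHS / kernel regression by Gibbs sampling
#'
#' Gaussian-process regression `y = mu + g + e`, `g ~ N(0, K sigma2_g)`,
#' sampled in the eigenbasis of the (training) kernel: writing
#' `g = U diag(sqrt(d)) alpha` with `alpha ~ N(0, sigma2_g I)` the conditional
#' of `alpha` is Gaussian with diagonal covariance, so whole-vector updates
#' are exact.  Eigenvalues below `1e-8` of the largest are truncated.
#'
#' @param K a `kernel_matrix` over the training individuals (PSD after
#'   [repair_psd()]).
#' @param y phenotypes aligned to the rows of `K`.
#' @param config a [gibbs_config()].
#' @return a `gp_fit` of model `"RKHS"`; prediction for new individuals uses
#'   cross-kernel rows (see [predict.gp_fit()]).
#' @export
fit_rkhs <- function(K, y, config = gibbs_config()) {
  K <- repair_psd(K)
  if (nrow(K) != length(y)) stop("kernel rows must align with y", call. = FALSE)
  if (anyNA(y)) stop("missing phenotypes not supported; subset first", call. = FALSE)
  if (var(y) <= 0) stop("constant phenotype; degenerate response", call. = FALSE)
  eb <- eigen_basis(K)
  res <- kernel_gibbs(list(eb), y, config)
  w <- eb$U %*% (res$alpha_mean[[1]] / sqrt(eb$d))   # K_tt^{-1} g_hat
  new_gp_fit("RKHS", res$mu, NULL,
             list(sigma2_g = res$s2k_draws[[1]], sigma2_e = res$s2e_draws),
             rownames(K), config,
             extra = list(g_mean = drop(res$g_mean[[1]]), kernel_weights = drop(w)))
}

#' Multi-kernel variance decomposition (A + D + E)
#'
#' Fits `y = mu + a + d + e + eps` with `a ~ N(0, A s2_a)`,
#' `d ~ N(0, D s2_d)`, `e ~ N(0, E s2_e)` by blockwise eigenbasis Gibbs
#' updates, and summarizes the posterior of the variance ratios
#' `h2_i = s2_i / (s2_a + s2_d + s2_e + s2_eps)` computed draw by draw.
#'
#' @param Ks named list of `kernel_matrix` objects, conventionally
#'   `list(A = , D = , E = )`, identical row order.
#' @inheritParams fit_rkhs
#' @return list with elements `fit` (a `gp_fit` of model `"multikernel"`) and
#'   `decomposition` (a `variance_decomp`: per-draw ratio samples plus
#'   posterior mean/sd summary).
#' @export
fit_multikernel <- function(Ks, y, config = gibbs_config()) {
  stopifnot(is.list(Ks), length(Ks) >= 2)
  ids <- rownames(Ks[[1]])
  for (K in Ks) {
    if (nrow(K) != length(y)) stop("kernel rows must align with y", call. = FALSE)
    if (!identical(rownames(K), ids)) stop("kernel id order mismatch", call. = FALSE)
  }
  if (var(y) <= 0) stop("constant phenotype; degenerate response", call. = FALSE)
  Ks <- lapply(Ks, repair_psd)
  ebs <- lapply(Ks, eigen_basis)
  res <- kernel_gibbs(ebs, y, config)
  nms <- names(Ks) %||% paste0("K", seq_along(Ks))
  ws <- lapply(seq_along(ebs), function(k) {
    drop(ebs[[k]]$U %*% (res$alpha_mean[[k]] / sqrt(ebs[[k]]$d)))
  })
  names(ws) <- nms
  vs <- c(stats::setNames(res$s2k_draws, paste0("sigma2_", nms)),
          list(sigma2_eps = res$s2e_draws))
  fit <- new_gp_fit("multikernel", res$mu, NULL, vs, ids, config,
                    extra = list(g_mean = stats::setNames(res$g_mean, nms),
                                 kernel_weights = ws))
  draws <- do.call(cbind, res$s2k_draws)
  tot <- rowSums(draws) + res$s2e_draws
  ratios <- draws / tot
  colnames(ratios) <- paste0("h2_", nms)
  samples <- tibble::as_tibble(ratios)
  summary <- tibble::tibble(
    component = nms,
    mean = colMeans(ratios),
    sd = apply(ratios, 2, sd)
  )
  decomp <- structure(list(samples = samples, summary = summary),
                      class = "variance_decomp")
  list(fit = fit, decomposition = decomp)
}

#' @export
print.variance_decomp <- function(x, ...) {
  cat("<variance_decomp> posterior variance ratios\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.variance_decomp <- function(x, ...) x$summary

# shared eigenbasis Gibbs core for one or several kernels
kernel_gibbs <- function(ebs, y, config) {
  n <- length(y)
  nk <- length(ebs)
  vy <- var(y)
  df <- config$prior_df
  r2 <- config$prior_R2
  ss_k <- (r2 * vy / nk) * (df + 2)
  ss_e <- ((1 - r2) * vy) * (df + 2)
  Uc <- lapply(ebs, function(e) sweep(e$U, 2, sqrt(e$d), `*`))
  Ut1 <- lapply(Uc, function(B) drop(crossprod(B, rep(1, n))))
  Uty <- lapply(Uc, function(B) drop(crossprod(B, y)))
  UtU <- vector("list", nk)  # cross-products between kernel bases
  for (k in seq_len(nk)) {
    UtU[[k]] <- lapply(seq_len(nk), function(l) crossprod(Uc[[k]], Uc[[l]]))
  }
  dvec <- lapply(ebs, `[[`, "d")
  alpha <- lapply(dvec, function(d) numeric(length(d)))
  g <- lapply(seq_len(nk), function(k) numeric(n))
  mu <- mean(y)
  s2k <- rep(r2 * vy / nk, nk)
  s2e <- (1 - r2) * vy
  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  s2k_draws <- lapply(seq_len(nk), function(k) numeric(n_keep))
  s2e_draws <- numeric(n_keep)
  alpha_mean <- lapply(dvec, function(d) numeric(length(d)))
  g_mean <- lapply(seq_len(nk), function(k) numeric(n))
  mu_mean <- 0
  keep <- 0
  set.seed(config$seed)
  for (it in seq_len(config$n_iter)) {
    gsum <- Reduce(`+`, g)
    mu <- mean(y - gsum) + rnorm(1) * sqrt(s2e / n)
    for (k in seq_len(nk)) {
      rhs <- Uty[[k]] - mu * Ut1[[k]]
      for (l in seq_len(nk)) {
        if (l != k) rhs <- rhs - drop(UtU[[k]][[l]] %*% alpha[[l]])
      }
      Cj <- dvec[[k]] + s2e / s2k[k]
      alpha[[k]] <- rhs / Cj + rnorm(length(Cj)) * sqrt(s2e / Cj)
      g[[k]] <- drop(Uc[[k]] %*% alpha[[k]])
      s2k[k] <- (ss_k + sum(alpha[[k]]^2)) / stats::rchisq(1, df + length(Cj))
    }
    e <- y - mu - Reduce(`+`, g)
    s2e <- (ss_e + sum(e^2)) / stats::rchisq(1, df + n)
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0 &&
        keep < n_keep) {
      keep <- keep + 1
      mu_mean <- mu_mean + mu
      for (k in seq_len(nk)) {
        s2k_draws[[k]][keep] <- s2k[k]
        alpha_mean[[k]] <- alpha_mean[[k]] + alpha[[k]]
        g_mean[[k]] <- g_mean[[k]] + g[[k]]
      }
      s2e_draws[keep] <- s2e
    }
  }
  list(mu = mu_mean / n_keep,
       alpha_mean = lapply(alpha_mean, `/`, n_keep),
       g_mean = lapply(g_mean, `/`, n_keep),
       s2k_draws = s2k_draws, s2e_draws = s2e_draws)
}

#' Predict genetic merit for new individuals
#'
#' For marker-effect models (`BRR`, `BL`, `BRR-GM`) `newdata` is a design
#' matrix with the same columns as training (aligned by column name when both
#' are named): prediction is `intercept + X_new %*% effects`.  For kernel
#' models (`RKHS`) `newdata` is the cross-kernel matrix `K[new, train]`
#' (aligned by training id when named), giving the conditional mean
#' `intercept + K_new,train K_train^{-1} g_hat`.  For `multikernel` fits,
#' `newdata` is a list of cross-kernel matrices in the order of the fitted
#' kernels.  Deterministic given the fit.
#'
#' @param object a `gp_fit`.
#' @param newdata see Details.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gp_fit <- function(object, newdata, ...) {
  if (object$model == "multikernel") {
    stopifnot(is.list(newdata), length(newdata) == length(object$kernel_weights))
    pred <- rep(object$intercept_mean, nrow(newdata[[1]]))
    for (k in seq_along(newdata)) {
      Kc <- align_cols(as.matrix(newdata[[k]]), object$training_ids)
      pred <- pred + drop(Kc %*% object$kernel_weights[[k]])
    }
    return(stats::setNames(pred, rownames(newdata[[1]])))
  }
  newdata <- as.matrix(newdata)
  if (object$model == "RKHS") {
    Kc <- align_cols(newdata, object$training_ids)
    return(stats::setNames(
      object$intercept_mean + drop(Kc %*% object$kernel_weights),
      rownames(newdata)))
  }
  Xn <- align_cols(newdata, names(object$effect_means))
  stats::setNames(object$intercept_mean + drop(Xn %*% object$effect_means),
                  rownames(newdata))
}

align_cols <- function(M, wanted) {
  if (is.null(wanted) || is.null(colnames(M))) {
    if (!is.null(wanted) && ncol(M) != length(wanted)) {
      stop("column count does not match training", call. = FALSE)
    }
    return(M)
  }
  if (!all(wanted %in% colnames(M))) {
    stop("newdata is missing training columns", call. = FALSE)
  }
  M[, wanted, drop = FALSE]
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("<gp_fit> model = %s, n_train = %d, retained draws = %d\n",
              x$model, length(x$training_ids),
              length(x$variance_samples[[1]])))
  invisible(x)
}

#' @export
tidy.gp_fit <- function(x, ...) {
  if (is.null(x$effect_means)) {
    return(tibble::tibble(term = "intercept", estimate = x$intercept_mean))
  }
  tibble::tibble(
    term = c("intercept", names(x$effect_means) %||%
               paste0("b", seq_along(x$effect_means))),
    estimate = c(x$intercept_mean, unname(x$effect_means))
  )
}

#' @export
glance.gp_fit <- function(x, ...) {
  vs <- purrr::map_dbl(x$variance_samples, mean)
  dplyr::bind_cols(
    tibble::tibble(model = x$model, n_train = length(x$training_ids),
                   n_draws = length(x$variance_samples[[1]])),
    tibble::as_tibble(as.list(vs))
  )
}
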