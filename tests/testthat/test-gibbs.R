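short_cfg <- function(seed = 1, ...) {
  gibbs_config(n_iter = 1200, burn_in = 200, seed = seed, ...)
}

test_that("retained draw counts follow the chain settings", {
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  fit <- fit_brr(X, y, gibbs_config(n_iter = 900, burn_in = 300, thin = 3,
                                    seed = 1))
  expect_length(fit$variance_samples$sigma2_e, 200)
  expect_true(all(fit$variance_samples$sigma2_b > 0))
  expect_true(all(fit$variance_samples$sigma2_e > 0))
})

test_that("chains are bitwise reproducible under a fixed seed", {
  set.seed(99)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  f1 <- fit_brr(X, y, short_cfg(7))
  f2 <- fit_brr(X, y, short_cfg(7))
  expect_identical(f1$variance_samples, f2$variance_samples)
  expect_identical(f1$effect_means, f2$effect_means)
  b1 <- fit_bl(X, y, short_cfg(7))
  b2 <- fit_bl(X, y, short_cfg(7))
  expect_identical(b1$effect_means, b2$effect_means)
})

test_that("null-signal BRR keeps effects indistinguishable from zero", {
  set.seed(3)
  X <- scale(matrix(rnorm(50 * 8), 50, 8))
  y <- rnorm(50, 0, 1e-3)
  fit <- fit_brr(X, y, short_cfg(4))
  expect_true(all(abs(fit$effect_means) < 1e-2))
})

test_that("fixed-variance BRR matches the closed-form ridge solution", {
  set.seed(5)
  X <- scale(matrix(rnorm(20 * 10), 20, 10), scale = FALSE)
  y <- rnorm(20) + X[, 1]
  s2b <- 0.4; s2e <- 1.2
  fit <- fit_brr(X, y, gibbs_config(12000, 2000, seed = 6,
                                    fixed_variances = list(sigma2_b = s2b,
                                                           sigma2_e = s2e)))
  ridge <- drop(solve(crossprod(X) + diag(s2e / s2b, 10),
                      crossprod(X, y - mean(y))))
  expect_equal(unname(fit$effect_means), ridge, tolerance = 0.02)
})

test_that("scaling the phenotype scales effects and variances accordingly", {
  set.seed(12)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40) + 0.5 * X[, 2]
  c0 <- 3.7
  f1 <- fit_brr(X, y, short_cfg(9))
  f2 <- fit_brr(X, c0 * y, short_cfg(9))
  expect_equal(f2$effect_means, c0 * f1$effect_means, tolerance = 1e-6)
  expect_equal(f2$variance_samples$sigma2_e,
               c0^2 * f1$variance_samples$sigma2_e, tolerance = 1e-6)
  b1 <- fit_bl(X, y, short_cfg(9))
  b2 <- fit_bl(X, c0 * y, short_cfg(9))
  expect_equal(b2$effect_means, c0 * b1$effect_means, tolerance = 1e-6)
})

test_that("Bayesian lasso shrinks harder than BRR on null signal, zeroes nothing", {
  set.seed(21)
  X <- scale(matrix(rnorm(60 * 30), 60, 30))
  y <- rnorm(60)
  brr <- fit_brr(X, y, short_cfg(2))
  bl <- fit_bl(X, y, short_cfg(2))
  expect_true(all(bl$effect_means != 0))
  expect_true(all(is.finite(bl$effect_means)))
  expect_lt(mean(abs(bl$effect_means)), mean(abs(brr$effect_means)))
})

test_that("Bayesian lasso estimates sparse effects at least as well as BRR", {
  errs <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 120; p <- 200
    X <- scale(matrix(rnorm(n * p), n, p))
    beta <- numeric(p); beta[1:10] <- rnorm(10, 0, 1.5)
    y <- drop(X %*% beta) + rnorm(n)
    brr <- fit_brr(X, y, short_cfg(s))
    bl <- fit_bl(X, y, short_cfg(s))
    c(brr = mean((brr$effect_means - beta)^2),
      bl = mean((bl$effect_means - beta)^2))
  }, numeric(2))
  expect_lte(mean(errs["bl", ]), mean(errs["brr", ]))
})

test_that("RKHS with identity kernel predicts the intercept for new rows", {
  set.seed(31)
  y <- rnorm(25, 5)
  K <- kernel_matrix(diag(25), "gaussian")
  rownames(K) <- colnames(K) <- paste0("i", 1:25)
  fit <- fit_rkhs(K, y, short_cfg(3))
  cross <- matrix(0, 2, 25, dimnames = list(c("n1", "n2"), rownames(K)))
  pred <- predict(fit, cross)
  expect_equal(unname(pred), rep(fit$intercept_mean, 2))
})

test_that("RKHS propagates fitted values through perfectly correlated individuals", {
  set.seed(32)
  g <- simulate_genotypes(30, 80, seed = 33)
  d <- g$dosages
  d <- rbind(d, dup = d[1, ])            # individual 31 duplicates 1
  rownames(d) <- paste0("i", 1:31)
  K <- additive_kernel(geno_matrix(d, 2))
  y <- rnorm(30)
  tr <- 1:30
  fit <- fit_rkhs(subset_kernel(K, tr, tr), y, short_cfg(5))
  pred <- predict(fit, unclass(K)[31, tr, drop = FALSE])
  fitted1 <- fit$intercept_mean + fit$g_mean[1]
  expect_equal(unname(pred), unname(fitted1), tolerance = 1e-6)
})

test_that("multikernel ratios behave algebraically and recover architecture", {
  # forced equal variance draws give ratio 0.25 each
  draws <- matrix(2, 10, 3)
  tot <- rowSums(draws) + 2
  expect_true(all(draws / tot == 0.25))
  # one small additive replicate: additive ratio dominates epistatic leak
  rep <- simulate_replicate(300, 600, 2, "additive", 0.5, seed = 41)
  A <- additive_kernel(rep$genotypes)
  D <- dominance_kernel_diploid(rep$genotypes)
  E <- epistasis_kernel(A)
  mk <- fit_multikernel(list(a = A, d = D, e = E), rep$trait$phenotypes,
                        short_cfg(42))
  s <- mk$decomposition$summary
  expect_equal(s$component, c("a", "d", "e"))
  expect_true(all(s$mean >= 0 & s$mean <= 1))
  expect_lte(sum(s$mean), 1)
  expect_gt(s$mean[s$component == "a"], s$mean[s$component == "e"])
  expect_error(
    fit_multikernel(list(a = A, d = subset_kernel(D, 1:10, 1:10)),
                    rep$trait$phenotypes, short_cfg(1)),
    "align|dimension|mismatch")
})

test_that("BRR-GM nests additivity and captures pure dominance patterns", {
  set.seed(51)
  g <- simulate_genotypes(150, 60, ploidy = 2, seed = 52)
  # pure dominance trait: phenotype depends only on heterozygosity at marker 1
  het <- as.numeric(g$dosages[, 1] == 1)
  y <- 2 * het + rnorm(150, 0, 0.5)
  gm <- fit_brr_gm(g, y, short_cfg(53))
  expect_identical(gm$model, "BRR-GM")
  Z <- additive_design(g)
  brr <- fit_brr(Z, y, short_cfg(53))
  om <- dosage_dummy_matrix(g)
  r2 <- function(pred) cor(pred, y)^2
  expect_gt(r2(predict(gm, om)), r2(predict(brr, Z)))
})

test_that("prediction is deterministic, alignment-aware and intercept-anchored", {
  set.seed(61)
  X <- matrix(rnorm(30 * 5), 30, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  y <- rnorm(30) + X[, 3]
  fit <- fit_brr(X, y, short_cfg(62))
  # training row reproduces its fitted value
  expect_equal(unname(predict(fit, X[3, , drop = FALSE])),
               fit$intercept_mean + sum(X[3, ] * fit$effect_means))
  # zero design row gives the intercept
  zero <- matrix(0, 1, 5, dimnames = list(NULL, paste0("m", 1:5)))
  expect_equal(unname(predict(fit, zero)), fit$intercept_mean)
  # permuted columns with names realign
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(predict(fit, X[, perm]), predict(fit, X))
  expect_error(predict(fit, X[, 1:3]), "missing training columns")
})

test_that("degenerate inputs are rejected with clear errors", {
  X <- matrix(rnorm(30), 10, 3)
  expect_error(fit_brr(X, rep(1, 10)), "constant")
  expect_error(fit_brr(X, rnorm(9)), "rows")
  Xn <- X; Xn[1, 1] <- NA
  expect_error(fit_brr(Xn, rnorm(10)), "missing")
})
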