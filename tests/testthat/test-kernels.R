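test_that("QC filter applies the MAF and missingness rules", {
  d <- cbind(
    c(rep(0, 99), 1),            # freq 0.005
    c(rep(0, 90), rep(1, 10)),   # freq 0.05
    c(rep(0, 80), rep(1, 20)),   # freq 0.10
    rep(c(0, 2), 50),            # freq 0.50
    rep(0, 100)                  # monomorphic
  )
  g <- geno_matrix(d, 2)
  kept <- filter_markers(g, maf_min = 0.05, missing_max = 1)
  expect_equal(ncol(kept$dosages), 3)
  expect_equal(unname(kept$allele_freq), c(0.05, 0.10, 0.50))
  # no-op thresholds return input unchanged
  same <- filter_markers(g, maf_min = 0, missing_max = 1)
  expect_equal(same$dosages, g$dosages)
  # > 5% missing removed at missing_max = 0.05
  d2 <- cbind(c(rep(NA, 6), rep(1, 94)), rep(0:1, 50))
  g2 <- geno_matrix(d2, 2)
  expect_equal(ncol(filter_markers(g2, 0, 0.05)$dosages), 1)
  expect_error(filter_markers(geno_matrix(matrix(0, 5, 1), 2), 0.05, 1),
               "all markers")
})

test_that("mean imputation fills missing entries with the observed mean", {
  g <- geno_matrix(matrix(c(0, 2, NA), ncol = 1), 2)
  expect_equal(unname(impute_mean(g)$dosages[, 1]), c(0, 2, 1))
  g2 <- geno_matrix(matrix(c(4, NA, NA, 0), ncol = 1), 4)
  expect_equal(unname(impute_mean(g2)$dosages[, 1]), c(4, 2, 2, 0))
  g3 <- random_panel()
  expect_equal(impute_mean(g3)$dosages, g3$dosages)
  g4 <- geno_matrix(matrix(NA_real_, 3, 1), 2)
  expect_error(impute_mean(g4), "M0001")
})

test_that("diploidization pools heterozygous classes", {
  g <- geno_matrix(matrix(0:4, ncol = 1), 4)
  expect_equal(unname(diploidize(g)$dosages[, 1]), c(0, 1, 1, 1, 2))
  expect_equal(diploidize(g)$ploidy, 2L)
  g2 <- random_panel(ploidy = 2)
  expect_identical(diploidize(g2)$dosages, g2$dosages)
  g6 <- geno_matrix(matrix(c(0, 6), ncol = 1), 6)
  expect_equal(unname(diploidize(g6)$dosages[, 1]), c(0, 2))
  gi <- impute_mean(geno_matrix(matrix(c(0, 1, NA), ncol = 1), 4))
  expect_error(diploidize(gi), "integer")
})

test_that("the centered additive design has zero column means", {
  g <- tiny_diploid()
  expect_equal(unname(additive_design(g)[, 1]), c(-1, 0, 1))
  g2 <- geno_matrix(matrix(1, 1, 1), 4)  # p = 0.25, dosage 1 -> 0
  expect_equal(unname(additive_design(g2)[1, 1]), 0)
  g3 <- random_panel(20, 8)
  expect_true(all(abs(colMeans(additive_design(g3))) < 1e-10))
})

test_that("worked diploid A, D and E matrices are reproduced exactly", {
  g <- tiny_diploid()
  A <- additive_kernel(g)
  expect_equal(unclass(A),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3),
               ignore_attr = TRUE)
  D <- dominance_kernel_diploid(g)
  expect_equal(unclass(D),
               matrix(c(1, -1, 1, -1, 1, -1, 1, -1, 1), 3),
               ignore_attr = TRUE)
  E <- epistasis_kernel(A)
  expect_equal(unclass(E), unclass(A)^2, ignore_attr = TRUE)
  expect_equal(diag(unclass(E)), diag(unclass(A))^2)
})

test_that("A, D, E match loop-based evaluation of the printed formulas", {
  for (seed in 1:5) {
    g <- random_panel(6, 5, seed = seed)
    expect_equal(unclass(additive_kernel(g)), brute_A(g),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unclass(dominance_kernel_diploid(g)), brute_D_diploid(g),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unclass(epistasis_kernel(additive_kernel(g))),
                 brute_A(g)^2, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("kernels are symmetric, PSD and permutation-equivariant", {
  g <- simulate_genotypes(30, 40, ploidy = 2, seed = 17)
  builders <- list(
    additive = additive_kernel,
    dominance = dominance_kernel_diploid,
    epistatic = function(x) epistasis_kernel(additive_kernel(x)),
    gaussian = function(x) gaussian_kernel(x, h = 1)
  )
  perm <- sample(nrow(g$dosages))
  gp <- geno_matrix(g$dosages[perm, ], g$ploidy)
  for (nm in names(builders)) {
    K <- builders[[nm]](g)
    expect_true(isSymmetric(unclass(K), tol = 1e-10), info = nm)
    ev <- min(eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values)
    expect_gte(ev, -1e-8)
    Kp <- builders[[nm]](gp)
    expect_equal(unclass(Kp), unclass(K)[perm, perm],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("A on HWE diploid data has mean self-relationship near 1", {
  g <- simulate_genotypes(500, 1000, ploidy = 2, ld_block_size = 1, seed = 23)
  A <- additive_kernel(g)
  expect_lt(abs(mean(diag(unclass(A))) - 1), 0.05)
  # duplicated individuals share all relationship entries
  d <- g$dosages[c(1, 1, 2), ]
  rownames(d) <- c("a", "b", "c")
  A2 <- additive_kernel(geno_matrix(d, 2))
  expect_equal(A2["a", "a"], A2["a", "b"])
  expect_equal(A2["a", "a"], A2["b", "b"])
})

test_that("Schur product theorem holds numerically for epistatic kernels", {
  for (seed in 1:100) {
    set.seed(seed)
    B <- matrix(rnorm(20 * 5), 20, 5)
    A <- kernel_matrix(tcrossprod(B) / 5, "additive")
    E <- epistasis_kernel(A)
    ev <- min(eigen(unclass(E), symmetric = TRUE, only.values = TRUE)$values)
    expect_gte(ev, -1e-8)
  }
})

test_that("tetraploid dominance uses the digenic heterozygosity covariate", {
  # q(4-q) enumerates to 0, 3, 4, 3, 0
  expect_equal((0:4) * (4 - 0:4), c(0, 3, 4, 3, 0))
  d <- matrix(c(0, 4, 2, 1, 0, 4, 3, 2), nrow = 4)
  g <- geno_matrix(d, 4)
  D <- dominance_kernel_tetraploid(g)
  expect_true(isSymmetric(unclass(D), tol = 1e-10))
  expect_lt(abs(mean(diag(unclass(D))) - 1), 1e-10)
  # dosage 0 and dosage 4 share the raw covariate 0, so two individuals
  # differing only by that swap get identical rows
  d2 <- matrix(c(0, 4, 1,
                 2, 2, 3,
                 1, 1, 0), nrow = 3)
  D2 <- dominance_kernel_tetraploid(geno_matrix(d2, 4))
  expect_equal(unclass(D2)[1, ], unclass(D2)[2, ], ignore_attr = TRUE)
  expect_warning(
    dominance_kernel_tetraploid(geno_matrix(matrix(2, 3, 2), 4)),
    "no dominance variation")
  expect_error(dominance_kernel_tetraploid(random_panel(ploidy = 2)), "ploidy 4")
  expect_error(dominance_kernel_diploid(simulate_genotypes(5, 5, 4, seed = 1)),
               "ploidy 2")
})

test_that("additive kernel commutes with diploidized coding", {
  g4 <- simulate_genotypes(25, 30, ploidy = 4, seed = 19)
  g2 <- diploidize(g4)
  native <- geno_matrix(g2$dosages, 2)   # same recoded dosages, native diploid
  expect_equal(unclass(additive_kernel(g2)), unclass(additive_kernel(native)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dosage dummy matrix indicates classes then centers and scales", {
  g <- geno_matrix(matrix(c(0, 1, 2, 1), ncol = 1), 2)
  X <- dosage_dummy_matrix(g)
  expect_equal(ncol(X), 3)
  expect_true(all(abs(colMeans(X)) < 1e-10))
  expect_equal(unname(apply(X, 2, sd)), rep(1, 3))
  # raw indicator pattern survives the affine transform: class-1 column
  # separates the two heterozygotes from the rest
  expect_equal(X[2, "M0001.1"], X[4, "M0001.1"])
  expect_gt(X[2, "M0001.1"], X[1, "M0001.1"])
  # tetraploid marker: up to 5 classes
  g4 <- geno_matrix(matrix(c(0, 1, 2, 3, 4), ncol = 1), 4)
  expect_equal(ncol(dosage_dummy_matrix(g4)), 5)
  # constant marker drops all its columns
  g5 <- geno_matrix(cbind(c(0, 1, 2, 1), rep(2, 4)), 2)
  X5 <- dosage_dummy_matrix(g5)
  expect_equal(ncol(X5), 3)
  expect_true(all(startsWith(attr(X5, "dropped"), "M0002")))
})

test_that("Gaussian kernel has unit diagonal and the printed scaling", {
  g <- geno_matrix(matrix(c(0, 2, 1, 1, 1, 1, 1, 1), nrow = 2), 2)
  K <- gaussian_kernel(g, h = 1)       # d2 = 4 over p = 4 markers
  expect_equal(K[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(diag(unclass(K)), c(I0001 = 1, I0002 = 1))
  # identical rows give exactly 1; h -> 0 drives everything to 1
  g2 <- geno_matrix(matrix(c(1, 1, 0, 0), nrow = 2), 2)
  expect_equal(unname(gaussian_kernel(g2, h = 1)[1, 2]), 1)
  g3 <- random_panel(5, 6)
  expect_true(all(unclass(gaussian_kernel(g3, h = 1e-9)) > 0.999))
  expect_error(gaussian_kernel(g3, h = 0), "bandwidth")
})

test_that("repair_psd leaves valid kernels alone and fixes jittered ones", {
  g <- random_panel(8, 6)
  A <- additive_kernel(g)
  expect_identical(repair_psd(A), A)
  bad <- kernel_matrix(unclass(A) - diag(0.01, nrow(A)), "additive")
  expect_message(fixed <- repair_psd(bad), "jitter")
  ev <- min(eigen(unclass(fixed), symmetric = TRUE, only.values = TRUE)$values)
  expect_gte(ev, -1e-8)
  expect_false(is.null(attr(fixed, "jitter_applied")))
})
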