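#' Simulate polyploid allele-dosage genotypes
#'
#' Draws an individuals x markers dosage panel.  Each marker's reference-allele
#' frequency is drawn uniformly from `maf_range`; a dosage is the sum of
#' `ploidy` allele indicators.  Within an LD block of `ld_block_size` adjacent
#' markers the latent allele states of each chromosome copy follow a Gaussian
#' AR(1) process (correlation `ld_rho` between neighbours, decaying with
#' distance), so nearby markers are correlated while marginal frequencies are
#' preserved exactly.  Blocks, copies and individuals are independent.
#'
#' @param n number of individuals.
#' @param p number of markers.
#' @param ploidy even integer >= 2.
#' @param maf_range length-2 numeric `(low, high)` with `0 < low <= high <= 0.5`;
#'   marker allele frequencies are drawn uniformly in this interval.
#' @param ld_block_size markers per LD block; 1 gives fully independent markers.
#' @param ld_rho neighbour correlation of the latent AR(1) state within a block.
#' @param missing_rate fraction of entries set missing completely at random.
#' @param seed integer seed; the draw is fully reproducible given it.
#' @return a [geno_matrix()].
#' @examples
#' g <- simulate_genotypes(50, 20, ploidy = 4, seed = 1)
#' range(g$dosages)
#' @export
simulate_genotypes <- function(n, p, ploidy = 2,
                               maf_range = c(0.05, 0.5),
                               ld_block_size = 10, ld_rho = 0.9,
                               missing_rate = 0, seed = 1) {
  check_ploidy(ploidy)
  if (n < 1 || p < 1) stop("n and p must be >= 1", call. = FALSE)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must satisfy 0 < low <= high <= 0.5", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (ld_block_size < 1) stop("ld_block_size must be >= 1", call. = FALSE)
  set.seed(seed)
  freq <- runif(p, maf_range[1], maf_range[2])
  thr <- qnorm(freq)
  dos <- matrix(0, n, p)
  block_start <- ((seq_len(p) - 1) %% ld_block_size) == 0
  a <- sqrt(1 - ld_rho^2)
  for (cp in seq_len(ploidy)) {
    z <- matrix(rnorm(n * p), n, p)
    if (ld_block_size > 1 && p > 1) {
      for (j in 2:p) {
        if (!block_start[j]) z[, j] <- ld_rho * z[, j - 1] + a * z[, j]
      }
    }
    dos <- dos + sweep(z, 2, thr, `<`)
  }
  if (missing_rate > 0) {
    dos[runif(length(dos)) < missing_rate] <- NA
  }
  geno_matrix(dos, ploidy)
}

#' Sample a trait architecture
#'
#' Chooses causal additive loci and/or multiplicative epistatic marker pairs
#' uniformly without replacement (additive loci and pair members are mutually
#' disjoint), and samples one effect per locus / pair with magnitude
#' `Gamma(shape = gamma_shape, scale = gamma_scale)` and a random +/- sign.
#' Kind-specific default sizes follow the three study architectures:
#' `additive` = 200 loci, `epistatic` = 100 pairs, `mixed` = 80 loci + 60 pairs.
#'
#' @param genotypes a [geno_matrix()]; only its marker count is used.
#' @param kind `"additive"`, `"epistatic"` or `"mixed"`.
#' @param n_additive,n_pairs numbers of causal loci / pairs; `NULL` picks the
#'   kind-specific default.
#' @param gamma_shape,gamma_scale shape and scale of the gamma distribution of
#'   effect magnitudes (defaults 1 and 0.2).
#' @param seed integer seed.
#' @return an object of class `trait_architecture` with elements `kind`,
#'   `additive_loci`, `additive_effects`, `epistatic_pairs` (2-column matrix),
#'   `pair_effects`, `gamma_shape`, `gamma_scale`.
#' @examples
#' g <- simulate_genotypes(20, 500, seed = 1)
#' a <- sample_architecture(g, "mixed", seed = 2)
#' length(a$additive_loci)
#' @export
sample_architecture <- function(genotypes, kind = c("additive", "epistatic", "mixed"),
                                n_additive = NULL, n_pairs = NULL,
                                gamma_shape = 1, gamma_scale = 0.2, seed = 1) {
  kind <- match.arg(kind)
  p <- ncol(genotypes$dosages)
  defaults <- switch(kind,
    additive  = c(200L, 0L),
    epistatic = c(0L, 100L),
    mixed     = c(80L, 60L)
  )
  if (is.null(n_additive)) n_additive <- defaults[1]
  if (is.null(n_pairs)) n_pairs <- defaults[2]
  if (kind == "additive" && n_pairs > 0) stop("additive kind takes no pairs", call. = FALSE)
  if (kind == "epistatic" && n_additive > 0) stop("epistatic kind takes no additive loci", call. = FALSE)
  if (kind == "mixed" && (n_additive == 0 || n_pairs == 0)) {
    stop("mixed kind needs both additive loci and pairs", call. = FALSE)
  }
  need <- n_additive + 2 * n_pairs
  if (need > p) {
    stop(sprintf("architecture needs %d distinct markers but only %d available",
                 need, p), call. = FALSE)
  }
  set.seed(seed)
  idx <- sample.int(p, need)
  add <- if (n_additive > 0) idx[seq_len(n_additive)] else integer(0)
  pr <- if (n_pairs > 0) {
    matrix(idx[n_additive + seq_len(2 * n_pairs)], ncol = 2)
  } else {
    matrix(integer(0), ncol = 2)
  }
  n_eff <- n_additive + n_pairs
  mag <- rgamma(n_eff, shape = gamma_shape, scale = gamma_scale)
  sgn <- sample(c(-1, 1), n_eff, replace = TRUE)
  eff <- mag * sgn
  structure(
    list(kind = kind,
         additive_loci = add,
         additive_effects = eff[seq_len(n_additive)],
         epistatic_pairs = pr,
         pair_effects = if (n_pairs > 0) eff[n_additive + seq_len(n_pairs)] else numeric(0),
         gamma_shape = gamma_shape, gamma_scale = gamma_scale),
    class = "trait_architecture"
  )
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf("<trait_architecture> kind = %s: %d additive loci, %d epistatic pairs\n",
              x$kind, length(x$additive_loci), nrow(x$epistatic_pairs)))
  invisible(x)
}

#' @export
tidy.trait_architecture <- function(x, ...) {
  add <- tibble::tibble(term = "additive", locus1 = x$additive_loci,
                        locus2 = NA_integer_, effect = x$additive_effects)
  ep <- tibble::tibble(term = "epistatic",
                       locus1 = x$epistatic_pairs[, 1],
                       locus2 = x$epistatic_pairs[, 2],
                       effect = x$pair_effects)
  dplyr::bind_rows(add, ep)
}

#' Total genetic value of each individual
#'
#' Additive loci contribute `effect * dosage`; each epistatic pair contributes
#' `effect * dosage1 * dosage2` (raw multiplicative dosage product, not
#' centered).  Deterministic.
#'
#' @param genotypes a [geno_matrix()] with no missing entries at causal loci.
#' @param arch a [sample_architecture()] result.
#' @return numeric vector of genetic values, one per individual.
#' @export
compute_genetic_values <- function(genotypes, arch) {
  d <- genotypes$dosages
  causal <- c(arch$additive_loci, as.vector(arch$epistatic_pairs))
  if (length(causal) && anyNA(d[, causal])) {
    stop("missing dosages at causal loci; impute first", call. = FALSE)
  }
  g <- numeric(nrow(d))
  if (length(arch$additive_loci)) {
    g <- g + drop(d[, arch$additive_loci, drop = FALSE] %*% arch$additive_effects)
  }
  if (nrow(arch$epistatic_pairs)) {
    prod_mat <- d[, arch$epistatic_pairs[, 1], drop = FALSE] *
      d[, arch$epistatic_pairs[, 2], drop = FALSE]
    g <- g + drop(prod_mat %*% arch$pair_effects)
  }
  names(g) <- rownames(d)
  g
}

#' Simulate phenotypes at a target broad-sense heritability
#'
#' Adds a normal residual to the genetic values with variance calibrated as
#' `var(g) * (1 - H2) / H2`, so the expected broad-sense heritability
#' (genetic variance over phenotypic variance) equals `target_H2`.
#'
#' @param genetic_values numeric vector with positive variance.
#' @param target_H2 target broad-sense heritability in `(0, 1]`.
#' @param seed integer seed.
#' @return an object of class `sim_trait`: list with `genetic_values`,
#'   `phenotypes`, `residual_variance` and `realized_H2`
#'   (= empirical `var(g)/var(y)`).
#' @examples
#' g <- rnorm(100)
#' tr <- simulate_phenotypes(g, 0.5, seed = 1)
#' tr$realized_H2
#' @export
simulate_phenotypes <- function(genetic_values, target_H2, seed = 1) {
  if (target_H2 <= 0 || target_H2 > 1) stop("target_H2 must be in (0, 1]", call. = FALSE)
  vg <- var(genetic_values)
  if (!is.finite(vg) || vg <= 0) {
    stop("genetic values are constant; degenerate trait", call. = FALSE)
  }
  sigma2 <- vg * (1 - target_H2) / target_H2
  set.seed(seed)
  y <- genetic_values +
    if (sigma2 > 0) rnorm(length(genetic_values), 0, sqrt(sigma2)) else 0
  structure(
    list(genetic_values = genetic_values, phenotypes = y,
         residual_variance = sigma2, realized_H2 = vg / var(y)),
    class = "sim_trait"
  )
}

#' @export
print.sim_trait <- function(x, ...) {
  cat(sprintf("<sim_trait> n = %d, residual variance = %.4g, realized H2 = %.3f\n",
              length(x$phenotypes), x$residual_variance, x$realized_H2))
  invisible(x)
}

#' @export
tidy.sim_trait <- function(x, ...) {
  tibble::tibble(
    individual = names(x$phenotypes) %||% as.character(seq_along(x$phenotypes)),
    genetic_value = unname(x$genetic_values),
    phenotype = unname(x$phenotypes)
  )
}

#' Simulate a full replicate: genotypes, architecture, trait
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [sample_architecture()] and [simulate_phenotypes()] with sub-seeds derived
#' from one replicate seed.
#'
#' @inheritParams simulate_genotypes
#' @inheritParams sample_architecture
#' @param target_H2 target broad-sense heritability.
#' @return list with `genotypes`, `architecture`, `trait`.
#' @export
simulate_replicate <- function(n, p, ploidy = 2, kind = "additive",
                               target_H2 = 0.5, maf_range = c(0.05, 0.5),
                               ld_block_size = 10, missing_rate = 0, seed = 1,
                               n_additive = NULL, n_pairs = NULL,
                               gamma_shape = 1, gamma_scale = 0.2) {
  g <- simulate_genotypes(n, p, ploidy, maf_range, ld_block_size,
                          missing_rate = missing_rate, seed = seed)
  arch <- sample_architecture(g, kind, n_additive, n_pairs,
                              gamma_shape, gamma_scale, seed = seed + 1L)
  gi <- if (anyNA(g$dosages)) impute_mean(g) else g
  gv <- compute_genetic_values(gi, arch)
  trait <- simulate_phenotypes(gv, target_H2, seed = seed + 2L)
  list(genotypes = g, architecture = arch, trait = trait)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
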