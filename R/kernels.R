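#' Genomic relationship kernels and design matrices
#'
#' Constructors for the matrices used by the Bayesian models: the centered
#' additive design `Z`, the additive relationship `A = Z Z' / c` with
#' `c = sum_j m p_j (1 - p_j)` for ploidy `m` (the diploid `2 sum p(1-p)`
#' generalized so the mean self-relationship stays near 1), the dominance
#' relationship `D` (diploid and autotetraploid codings), the epistatic
#' relationship `E = A (Hadamard) A`, the per-dosage-class dummy design
#' `Omega`, and the Gaussian kernel
#' `K(x_i, x_k) = exp(-h * ||x_i - x_k||^2 / p)`.
#'
#' Kernels are returned as `kernel_matrix` objects: a plain symmetric matrix
#' with attributes `kind` and `denominator`; [repair_psd()] adds a diagonal
#' jitter when numerical noise drives the minimum eigenvalue below tolerance.
#'
#' @name kernels
NULL

kernel_matrix <- function(values, kind, denominator = NA_real_) {
  values <- (values + t(values)) / 2   # enforce exact symmetry
  structure(values, kind = kind, denominator = denominator,
            class = c("kernel_matrix", "matrix", "array"))
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> kind = %s, %d x %d, mean diagonal = %.3f\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

#' @rdname kernels
#' @param genotypes a [geno_matrix()] with no missing entries.
#' @return `additive_design()`: numeric matrix `Z` with
#'   `Z[i, j] = dosage[i, j] - ploidy * p_j` (all column means 0).
#' @export
additive_design <- function(genotypes) {
  d <- genotypes$dosages
  if (anyNA(d)) stop("missing dosages; impute first", call. = FALSE)
  Z <- sweep(d, 2, genotypes$ploidy * genotypes$allele_freq)
  attr(Z, "centered") <- TRUE
  Z
}

#' @rdname kernels
#' @return `additive_kernel()`: `kernel_matrix` of kind `"additive"`.
#' @export
additive_kernel <- function(genotypes) {
  Z <- additive_design(genotypes)
  p <- genotypes$allele_freq
  denom <- sum(genotypes$ploidy * p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic; zero denominator", call. = FALSE)
  kernel_matrix(tcrossprod(Z) / denom, "additive", denom)
}

#' @rdname kernels
#' @return `dominance_kernel_diploid()`: `kernel_matrix` of kind `"dominance"`
#'   built from the classical diploid coding `-2p^2, 2p(1-p), -2(1-p)^2` for
#'   genotypes 0, 1, 2 with denominator `4 sum [p(1-p)]^2`.
#' @export
dominance_kernel_diploid <- function(genotypes) {
  if (genotypes$ploidy != 2) {
    stop("dominance_kernel_diploid requires ploidy 2 (see dominance_kernel_tetraploid)",
         call. = FALSE)
  }
  d <- genotypes$dosages
  if (anyNA(d)) stop("missing dosages; impute first", call. = FALSE)
  p <- genotypes$allele_freq
  # dosage-specific codes; fractional (imputed) dosages are rounded to class
  dr <- round(d)
  M <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  for (j in seq_len(ncol(d))) {
    codes <- c(-2 * p[j]^2, 2 * p[j] * (1 - p[j]), -2 * (1 - p[j])^2)
    M[, j] <- codes[dr[, j] + 1]
  }
  denom <- 4 * sum((p * (1 - p))^2)
  if (denom <= 0) stop("all markers monomorphic; zero denominator", call. = FALSE)
  kernel_matrix(tcrossprod(M) / denom, "dominance", denom)
}

#' @rdname kernels
#' @details The autotetraploid dominance coding uses the digenic
#'   heterozygosity covariate: for dosage `q` the number of heterozygous
#'   allele pairs among the `choose(4, 2) = 6` digenic combinations is
#'   `q * (4 - q)` (0, 3, 4, 3, 0 for q = 0..4).  Covariates are centered by
#'   their population mean and the cross-product matrix is normalized by the
#'   summed per-locus covariate variances, so the mean diagonal is 1.  This is
#'   an explicit in-package coding choice: published autotetraploid dominance
#'   matrices exist in several variants and none is canonical.
#' @return `dominance_kernel_tetraploid()`: `kernel_matrix` of kind
#'   `"dominance"`.
#' @export
dominance_kernel_tetraploid <- function(genotypes) {
  if (genotypes$ploidy != 4) {
    stop("dominance_kernel_tetraploid requires ploidy 4", call. = FALSE)
  }
  d <- genotypes$dosages
  if (anyNA(d)) stop("missing dosages; impute first", call. = FALSE)
  W <- d * (4 - d)                       # digenic heterozygosity count
  W <- sweep(W, 2, colMeans(W))
  denom <- sum(colSums(W^2) / nrow(W))   # summed population variances
  if (denom <= 0) {
    warning("no dominance variation in panel; returning zero matrix")
    return(kernel_matrix(matrix(0, nrow(d), nrow(d),
                                dimnames = list(rownames(d), rownames(d))),
                         "dominance", 0))
  }
  kernel_matrix(tcrossprod(W) / denom, "dominance", denom)
}

#' @rdname kernels
#' @param A an additive `kernel_matrix`.
#' @return `epistasis_kernel()`: `kernel_matrix` of kind `"epistatic"`, the
#'   Hadamard square `A * A` (PSD by the Schur product theorem).
#' @export
epistasis_kernel <- function(A) {
  if (!isSymmetric(unclass(A), tol = 1e-8)) stop("A must be symmetric", call. = FALSE)
  kernel_matrix(unclass(A) * unclass(A), "epistatic")
}

#' @rdname kernels
#' @return `dosage_dummy_matrix()`: centered and unit-scaled matrix of
#'   dosage-class indicators, `ploidy + 1` columns per marker before dropping
#'   zero-variance classes; column names `"<marker>.<class>"`, dropped column
#'   ids in attribute `dropped`.
#' @export
dosage_dummy_matrix <- function(genotypes) {
  d <- genotypes$dosages
  if (anyNA(d)) stop("missing dosages; impute first", call. = FALSE)
  m <- genotypes$ploidy
  dr <- round(d)
  n <- nrow(d)
  cols <- vector("list", ncol(d))
  for (j in seq_len(ncol(d))) {
    ind <- matrix(0, n, m + 1)
    ind[cbind(seq_len(n), dr[, j] + 1)] <- 1
    colnames(ind) <- paste0(colnames(d)[j], ".", 0:m)
    cols[[j]] <- ind
  }
  X <- do.call(cbind, cols)
  sds <- apply(X, 2, sd)
  keep <- sds > 0
  dropped <- colnames(X)[!keep]
  X <- scale(X[, keep, drop = FALSE])
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  rownames(X) <- rownames(d)
  attr(X, "dropped") <- dropped
  attr(X, "centered") <- TRUE
  X
}

#' @rdname kernels
#' @param h Gaussian bandwidth (> 0) controlling how fast covariance decays
#'   with genotype distance.
#' @param scale_by divisor applied to squared Euclidean distances; default
#'   `"markers"` divides by the marker count so `h` is panel-size free.  A
#'   number can be supplied instead.
#' @return `gaussian_kernel()`: `kernel_matrix` of kind `"gaussian"` with unit
#'   diagonal.
#' @export
gaussian_kernel <- function(genotypes, h = 1, scale_by = "markers") {
  if (h <= 0) stop("bandwidth h must be > 0", call. = FALSE)
  d <- genotypes$dosages
  if (anyNA(d)) stop("missing dosages; impute first", call. = FALSE)
  s <- if (identical(scale_by, "markers")) ncol(d) else as.numeric(scale_by)
  sq <- rowSums(d^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(d)
  d2[d2 < 0] <- 0
  K <- exp(-h * d2 / s)
  diag(K) <- 1
  dimnames(K) <- list(rownames(d), rownames(d))
  kernel_matrix(K, "gaussian")
}

#' Positive-semidefiniteness check and jitter repair
#'
#' Verifies that the minimum eigenvalue of a kernel is above `-tol`; when it
#' is not, adds `jitter` to the diagonal (once) and records the repair in
#' attribute `jitter_applied`.
#'
#' @param K a `kernel_matrix`.
#' @param tol eigenvalue tolerance (default 1e-8).
#' @param jitter diagonal jitter added on violation (default 1e-8).
#' @return the (possibly repaired) `kernel_matrix`.
#' @export
repair_psd <- function(K, tol = 1e-8, jitter = 1e-8) {
  ev <- min(eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -tol) {
    message(sprintf("kernel min eigenvalue %.3g < -%g; adding %g jitter",
                    ev, tol, jitter))
    Kj <- unclass(K) + diag(jitter - ev, nrow(K))
    K <- kernel_matrix(Kj, attr(K, "kind"), attr(K, "denominator"))
    attr(K, "jitter_applied") <- jitter - ev
  }
  K
}

#' @export
autoplot.kernel_matrix <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object), rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL, fill = attr(object, "kind"),
                  title = sprintf("%s relationship matrix", attr(object, "kind"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
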