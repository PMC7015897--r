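#' Marker quality control
#'
#' Retains markers whose minor allele frequency is at least `maf_min` and whose
#' missing fraction is at most `missing_max`; marker order is preserved.
#' Monomorphic markers (MAF 0) are always removed when `maf_min > 0`.
#'
#' @param genotypes a [geno_matrix()].
#' @param maf_min minimum minor allele frequency in `[0, 0.5]` (study default
#'   0.05, i.e. "MAF < 5% eliminated").
#' @param missing_max maximum tolerated missing fraction per marker (study
#'   default 0.05).
#' @return a filtered [geno_matrix()].
#' @export
filter_markers <- function(genotypes, maf_min = 0.05, missing_max = 0.05) {
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]", call. = FALSE)
  if (missing_max < 0 || missing_max > 1) stop("missing_max must be in [0, 1]", call. = FALSE)
  d <- genotypes$dosages
  maf <- pmin(genotypes$allele_freq, 1 - genotypes$allele_freq)
  missf <- colMeans(is.na(d))
  keep <- maf >= maf_min & missf <= missing_max & !is.na(maf)
  if (!any(keep)) stop("all markers removed by QC filter", call. = FALSE)
  genotypes[, keep]
}

#' Mean imputation of missing dosages
#'
#' Missing entries are replaced by the marker's mean observed dosage (a real
#' number); observed entries are untouched.
#'
#' @param genotypes a [geno_matrix()]; every marker must have at least one
#'   observed entry.
#' @return a [geno_matrix()] with no missing entries (dosages may be
#'   fractional).
#' @export
impute_mean <- function(genotypes) {
  d <- genotypes$dosages
  if (!anyNA(d)) return(genotypes)
  allna <- colSums(!is.na(d)) == 0
  if (any(allna)) {
    stop(sprintf("marker(s) with all entries missing: %s",
                 paste(colnames(d)[allna], collapse = ", ")), call. = FALSE)
  }
  mns <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mns[idx[, 2]]
  geno_matrix(d, genotypes$ploidy, require_integer = FALSE)
}

#' Diploidize polyploid dosages
#'
#' Pools all heterozygous dosage classes into one: dosage 0 stays 0, dosage
#' equal to the ploidy becomes 2, every intermediate dosage becomes 1 (e.g.
#' 0,1,2,3,4 -> 0,1,1,1,2 at ploidy 4).  The result has ploidy 2.  Must be
#' applied before mean imputation, since fractional dosages have no
#' heterozygosity class.
#'
#' @param genotypes a [geno_matrix()] with integer dosages.
#' @return a ploidy-2 [geno_matrix()].
#' @examples
#' g <- geno_matrix(matrix(0:4, nrow = 5, ncol = 1), ploidy = 4)
#' diploidize(g)$dosages[, 1]
#' @export
diploidize <- function(genotypes) {
  d <- genotypes$dosages
  ok <- d[!is.na(d)]
  if (length(ok) && any(abs(ok - round(ok)) > 1e-8)) {
    stop("diploidize requires integer dosages; diploidize before imputing",
         call. = FALSE)
  }
  if (genotypes$ploidy == 2) return(genotypes)
  out <- d
  out[!is.na(d) & d > 0 & d < genotypes$ploidy] <- 1
  out[!is.na(d) & d == genotypes$ploidy] <- 2
  geno_matrix(out, 2L)
}
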