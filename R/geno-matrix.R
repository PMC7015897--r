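#' Allele-dosage genotype matrix
#'
#' The universal input container of the package: an individuals x markers
#' matrix of reference-allele dosages (integers in `0..ploidy`, `NA` for
#' missing calls) together with the ploidy level and per-marker allele
#' frequencies.  Allele frequencies are always (re)computed from the stored
#' dosages as `mean(dosage) / ploidy` over non-missing entries, so the object
#' cannot drift out of sync with its own data.
#'
#' @param dosages numeric matrix, individuals in rows and markers in columns.
#'   Non-missing entries must lie in `[0, ploidy]`.  Row and column names are
#'   used as individual and marker ids; defaults (`I0001...`, `M0001...`) are
#'   supplied when absent.
#' @param ploidy even integer >= 2 (2 for diploids, 4 for autotetraploids...).
#' @param require_integer if `TRUE` (default) non-integer dosages are an
#'   error; mean imputation legitimately produces fractional dosages, so
#'   downstream constructors pass `FALSE`.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosages`,
#'   `ploidy` and `allele_freq`.
#' @examples
#' g <- geno_matrix(matrix(c(0, 2, 4, 1, 3, 0), nrow = 3), ploidy = 4)
#' allele_freq(g)
#' @export
geno_matrix <- function(dosages, ploidy, require_integer = TRUE) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  check_ploidy(ploidy)
  ok <- dosages[!is.na(dosages)]
  if (length(ok) && (any(ok < 0) || any(ok > ploidy))) {
    stop("dosages must lie in [0, ploidy]", call. = FALSE)
  }
  if (require_integer && length(ok) && any(abs(ok - round(ok)) > 1e-8)) {
    stop("dosages must be integers; use require_integer = FALSE for imputed data",
         call. = FALSE)
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("I%04d", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("M%04d", seq_len(ncol(dosages)))
  }
  af <- colMeans(dosages, na.rm = TRUE) / ploidy
  structure(
    list(dosages = dosages, ploidy = as.integer(ploidy), allele_freq = af),
    class = "geno_matrix"
  )
}

check_ploidy <- function(ploidy) {
  if (length(ploidy) != 1 || is.na(ploidy) || ploidy < 2 || ploidy %% 2 != 0) {
    stop("ploidy must be a single even integer >= 2", call. = FALSE)
  }
  invisible(ploidy)
}

#' @export
print.geno_matrix <- function(x, ...) {
  d <- x$dosages
  cat(sprintf("<geno_matrix> %d individuals x %d markers, ploidy %d\n",
              nrow(d), ncol(d), x$ploidy))
  miss <- mean(is.na(d))
  cat(sprintf("  missing: %.2f%%; allele freq range: [%.3f, %.3f]\n",
              100 * miss, min(x$allele_freq), max(x$allele_freq)))
  invisible(x)
}

#' @rdname geno_matrix
#' @param g a `geno_matrix`.
#' @export
allele_freq <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  g$allele_freq
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Individual / marker ids of a genotype matrix
#' @param g a `geno_matrix`.
#' @return character vector of ids.
#' @export
individual_ids <- function(g) rownames(g$dosages)

#' @rdname individual_ids
#' @export
marker_ids <- function(g) colnames(g$dosages)

#' Subset a genotype matrix by individuals and/or markers
#' @param x a `geno_matrix`.
#' @param i,j individual / marker indices (any form `[` accepts).
#' @param ... unused.
#' @return a `geno_matrix` with recomputed allele frequencies.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  d <- x$dosages[i, j, drop = FALSE]
  geno_matrix(d, x$ploidy, require_integer = FALSE)
}

#' @export
tidy.geno_matrix <- function(x, ...) {
  d <- x$dosages
  tibble::as_tibble(d, rownames = "individual") |>
    tidyr::pivot_longer(-"individual", names_to = "marker", values_to = "dosage")
}
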