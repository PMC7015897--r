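#' Read and write dosage genotype tables
#'
#' The on-disk convention is a plain TSV: one header row of marker ids, first
#' column `id` with individual ids, one integer (or imputed real) dosage per
#' cell, missing encoded as `NA`.
#'
#' @param genotypes a [geno_matrix()].
#' @param path file path.
#' @return `write_dosage_tsv()` returns `path` invisibly;
#'   `read_dosage_tsv()` returns a [geno_matrix()].
#' @export
write_dosage_tsv <- function(genotypes, path) {
  d <- genotypes$dosages
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @param ploidy ploidy of the stored panel (not inferrable from the file).
#' @export
read_dosage_tsv <- function(path, ploidy) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = NA)
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- df[[1]]
  geno_matrix(d, ploidy, require_integer = FALSE)
}

#' Read and write phenotype tables
#'
#' Two-column TSV: `id`, `value`.
#'
#' @param y named numeric vector (names are individual ids).
#' @param path file path.
#' @export
write_phenotype_tsv <- function(y, path) {
  write.table(data.frame(id = names(y), value = as.numeric(y)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  stats::setNames(df$value, df$id)
}

#' Write an architecture manifest
#'
#' Plain-text key-value listing of the causal loci, pairs and effects of a
#' [sample_architecture()] result, for parameter-recovery bookkeeping.
#'
#' @param arch a `trait_architecture`.
#' @param path file path.
#' @export
write_architecture_manifest <- function(arch, path) {
  lines <- c(
    paste0("kind: ", arch$kind),
    paste0("gamma_shape: ", arch$gamma_shape),
    paste0("gamma_scale: ", arch$gamma_scale),
    paste0("additive_loci: ", paste(arch$additive_loci, collapse = ",")),
    paste0("additive_effects: ", paste(format(arch$additive_effects, digits = 12),
                                       collapse = ",")),
    paste0("epistatic_pairs: ",
           paste(apply(arch$epistatic_pairs, 1, paste, collapse = ":"),
                 collapse = ",")),
    paste0("pair_effects: ", paste(format(arch$pair_effects, digits = 12),
                                   collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a kernel matrix as square TSV with a metadata sidecar
#'
#' The kernel goes to `path` (id header row and column); `paste0(path,
#' ".meta")` records kind, dimension and the normalizing denominator.
#'
#' @param K a `kernel_matrix`.
#' @param path file path.
#' @export
write_kernel_tsv <- function(K, path) {
  df <- data.frame(id = rownames(K), unclass(K), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("kind: ", attr(K, "kind")),
               paste0("n: ", nrow(K)),
               paste0("denominator: ", format(attr(K, "denominator")))),
             paste0(path, ".meta"))
  invisible(path)
}

#' Write genotypes as a dosage VCF
#'
#' Minimal VCF 4.3 with one pseudo-contig, one sample column per individual
#' and dosages in the `DS` FORMAT field (`GT` is set to `./.` as dosage data
#' carry no phase).  Readable back via [read_vcf_dosage()].
#'
#' @param genotypes a [geno_matrix()].
#' @param path file path (uncompressed `.vcf`).
#' @export
write_vcf_dosage <- function(genotypes, path) {
  d <- genotypes$dosages
  header <- c(
    "##fileformat=VCFv4.3",
    sprintf("##source=polyGP; ploidy=%d", genotypes$ploidy),
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(d)), function(j) {
    ds <- ifelse(is.na(d[, j]), ".", format(d[, j], trim = TRUE))
    paste(c("1", j, colnames(d)[j], "A", "B", ".", "PASS", ".",
            "GT:DS", paste0("./.:", ds)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_vcf_dosage
#' @param ploidy ploidy to assign to the panel; when `NULL` it is taken from
#'   the `##source` header line if present.
#' @export
read_vcf_dosage <- function(path, ploidy = NULL) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "##")]
  if (is.null(ploidy)) {
    src <- grep("ploidy=", meta, value = TRUE)
    if (length(src)) ploidy <- as.integer(sub(".*ploidy=(\\d+).*", "\\1", src[1]))
    if (is.null(ploidy) || is.na(ploidy)) {
      stop("ploidy not found in header; supply it", call. = FALSE)
    }
  }
  hdr <- lines[startsWith(lines, "#CHROM")]
  cols <- strsplit(hdr, "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t")
  markers <- vapply(fields, `[[`, character(1), 3)
  ds_index <- vapply(fields, function(f) {
    which(strsplit(f[9], ":")[[1]] == "DS")
  }, integer(1))
  d <- t(vapply(seq_along(fields), function(i) {
    vals <- vapply(strsplit(fields[[i]][-(1:9)], ":"), `[[`, character(1),
                   ds_index[i])
    suppressWarnings(as.numeric(ifelse(vals == ".", NA, vals)))
  }, numeric(length(samples))))
  dimnames(d) <- list(markers, samples)
  geno_matrix(t(d), ploidy, require_integer = FALSE)
}
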