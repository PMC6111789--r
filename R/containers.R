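#' Per-locus x per-sample read count table
#'
#' The central container of the genotyping side of the package: for each
#' biallelic locus and each sample, the number of reads supporting the
#' reference and the alternate allele. Each locus carries a ploidy context
#' (6x when its reads match both ancestral subgenomes, 4x / 2x when they are
#' specific to one of them).
#'
#' @param loci data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `ploidy` (one of 2, 4, 6).
#' @param ref,alt non-negative integer matrices, loci x samples, with sample
#'   names as column names.
#' @return an object of class `read_counts`.
#' @export
read_counts <- function(loci, ref, alt) {
  loci <- as.data.frame(loci)
  req <- c("chrom", "pos", "ref", "alt", "ploidy")
  if (!all(req %in% names(loci)))
    stop_param("loci must have columns ", paste(req, collapse = ", "))
  if (!all(loci$ploidy %in% c(2L, 4L, 6L)))
    stop_param("ploidy context must be one of 2, 4, 6")
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (!identical(dim(ref), dim(alt)))
    stop_param("ref and alt matrices must have identical dimensions")
  if (nrow(ref) != nrow(loci))
    stop_param("count matrices must have one row per locus")
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE))
    stop_param("read counts must be non-negative")
  if (is.null(colnames(ref)))
    colnames(ref) <- colnames(alt) <- paste0("S", seq_len(ncol(ref)))
  storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
  rownames(ref) <- rownames(alt) <- locus_ids(loci)
  structure(list(loci = loci, ref = ref, alt = alt), class = "read_counts")
}

locus_ids <- function(loci) {
  if (nrow(loci) == 0) return(character(0))
  paste0(loci$chrom, "_", loci$pos)
}

#' @export
print.read_counts <- function(x, ...) {
  cat("read_counts:", nrow(x$loci), "loci x", ncol(x$ref), "samples\n")
  cat("  ploidy contexts:",
      paste(names(table(x$loci$ploidy)), table(x$loci$ploidy),
            sep = "x:", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.read_counts <- function(x) dim(x$ref)

#' Allele-dosage genotype matrix
#'
#' Integer alternate-allele dosages in `0..ploidy` per locus and sample
#' (`NA` = missing / below depth threshold). The per-locus ploidy comes from
#' the locus table.
#'
#' @param loci locus data.frame as in [read_counts()].
#' @param dosages integer matrix, loci x samples; values in 0..ploidy or NA.
#' @return object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(loci, dosages) {
  loci <- as.data.frame(loci)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != nrow(loci))
    stop_param("dosage matrix must have one row per locus")
  bad <- sweep(dosages, 1, loci$ploidy, ">") | dosages < 0
  if (any(bad, na.rm = TRUE))
    stop_param("dosages must lie in 0..ploidy for each locus")
  rownames(dosages) <- locus_ids(loci)
  structure(list(loci = loci, dosages = dosages), class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", nrow(x$loci), "loci x", ncol(x$dosages), "samples;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' Diploidized genotype matrix
#'
#' Polyploid dosages collapsed to diploid-style codes: 0 (no alternate
#' allele), 2 (all alleles alternate), 1 (any intermediate dose), NA missing.
#' This is the input format of all diversity statistics.
#'
#' @param loci locus data.frame (ploidy column optional here).
#' @param codes integer matrix in \{0,1,2,NA\}, loci x samples.
#' @return object of class `diplo_matrix`.
#' @export
diplo_matrix <- function(loci, codes) {
  loci <- as.data.frame(loci)
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) != nrow(loci))
    stop_param("code matrix must have one row per locus")
  if (!all(codes %in% c(0L, 1L, 2L, NA)))
    stop_param("diploidized codes must be 0, 1, 2 or NA")
  rownames(codes) <- locus_ids(loci)
  structure(list(loci = loci, codes = codes), class = "diplo_matrix")
}

#' @export
print.diplo_matrix <- function(x, ...) {
  cat("diplo_matrix:", nrow(x$loci), "loci x", ncol(x$codes), "samples;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.diplo_matrix <- function(x) dim(x$codes)

sample_names <- function(x) {
  if (inherits(x, "read_counts")) colnames(x$ref)
  else if (inherits(x, "dosage_matrix")) colnames(x$dosages)
  else if (inherits(x, "diplo_matrix")) colnames(x$codes)
  else stop_param("unsupported object")
}
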