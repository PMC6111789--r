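# --- FASTQ ----------------------------------------------------------------

need_biostrings <- function() {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop_param("package Biostrings is required for FASTQ input/output")
}

#' Read a FASTQ file into a read data.frame
#'
#' @param path FASTQ path (Phred+33).
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  need_biostrings()
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read data.frame to FASTQ
#'
#' @param reads data.frame with `id`, `seq`, `qual` (Phred+33).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  need_biostrings()
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

# --- TSV dialects ---------------------------------------------------------

#' Write a read-count table as TSV
#'
#' Locus columns `chrom`, `pos`, `ref`, `alt`, `ploidy`, then one column
#' per sample with cells `"ref:alt"`.
#'
#' @param counts a [read_counts()] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "read_counts"))
  cells <- matrix(paste0(counts$ref, ":", counts$alt),
                  nrow(counts$ref), dimnames = dimnames(counts$ref))
  df <- cbind(counts$loci[, c("chrom", "pos", "ref", "alt", "ploidy")],
              as.data.frame(cells, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a read-count TSV written by [write_counts_tsv()]
#'
#' @param path input path.
#' @return a [read_counts()] object.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c(chrom = "character",
                                         ref = "character",
                                         alt = "character"))
  meta <- c("chrom", "pos", "ref", "alt", "ploidy")
  if (!all(meta %in% names(df)))
    stop_param("count TSV must start with columns ",
               paste(meta, collapse = ", "))
  cells <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  bad <- !grepl("^[0-9]+:[0-9]+$", cells)
  if (any(bad)) {
    ln <- which(rowSums(matrix(bad, nrow(cells))) > 0)[1]
    stop_param("unparseable count cell at data line ", ln,
               " (expected 'ref:alt')")
  }
  ref <- matrix(as.integer(sub(":.*", "", cells)), nrow(cells),
                dimnames = dimnames(cells))
  alt <- matrix(as.integer(sub(".*:", "", cells)), nrow(cells),
                dimnames = dimnames(cells))
  read_counts(df[, meta], ref, alt)
}

#' Write a genotype matrix (dosage or diploidized) as TSV
#'
#' Locus metadata columns followed by one integer column per sample
#' (`NA` for missing).
#'
#' @param m a [dosage_matrix()] or [diplo_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genotypes_tsv <- function(m, path) {
  g <- if (inherits(m, "dosage_matrix")) m$dosages else m$codes
  df <- cbind(m$loci[, intersect(c("chrom", "pos", "ref", "alt", "ploidy"),
                                 names(m$loci))],
              as.data.frame(g))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from TSV or VCF
#'
#' @param path input path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param kind `"dosage"` or `"diplo"`: how to type the values (VCF input
#'   always yields dosages).
#' @return a [dosage_matrix()] or [diplo_matrix()].
#' @export
read_genotype_matrix <- function(path, format = c("auto", "tsv", "vcf"),
                                 kind = c("dosage", "diplo")) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") return(read_vcf_dosage(path))
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  cls <- c(chrom = "character", ref = "character", alt = "character")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = cls[names(cls) %in% first])
  meta_cols <- intersect(c("chrom", "pos", "ref", "alt", "ploidy"), names(df))
  g <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  storage.mode(g) <- "integer"
  loci <- df[, meta_cols, drop = FALSE]
  if (!"ploidy" %in% names(loci)) loci$ploidy <- 2L
  if (!all(loci$ploidy %in% c(2L, 4L, 6L)))
    stop_param("ploidy context values must be 2, 4 or 6")
  if (kind == "dosage") dosage_matrix(loci, g) else diplo_matrix(loci, g)
}

# --- VCF ------------------------------------------------------------------

#' Write dosage calls (and read counts) as VCF 4.2
#'
#' Genotypes are ploidy-length GT strings whose alternate-allele count is
#' the dosage (e.g. `0/0/0/0/0/1` for dosage 1 at a 6x locus), with `AD`
#' (ref,alt) and `DP` when counts are supplied; the locus ploidy context is
#' the INFO key `PC`.
#'
#' @param m a [dosage_matrix()].
#' @param path output path.
#' @param counts optional matching [read_counts()] for AD/DP.
#' @return the path, invisibly.
#' @export
write_vcf <- function(m, path, counts = NULL) {
  stopifnot(inherits(m, "dosage_matrix"))
  samples <- colnames(m$dosages)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=polygbs",
    "##INFO=<ID=PC,Number=1,Type=Integer,Description=\"Ploidy context (2/4/6)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  fmt <- if (is.null(counts)) "GT" else "GT:AD:DP"
  lines <- vapply(seq_len(nrow(m$loci)), function(i) {
    p <- m$loci$ploidy[i]
    gt <- vapply(m$dosages[i, ], function(d) {
      if (is.na(d)) paste(rep(".", p), collapse = "/")
      else paste(c(rep("0", p - d), rep("1", d)), collapse = "/")
    }, "")
    cells <- if (is.null(counts)) gt else
      paste0(gt, ":", counts$ref[i, ], ",", counts$alt[i, ], ":",
             counts$ref[i, ] + counts$alt[i, ])
    paste(c(m$loci$chrom[i], m$loci$pos[i], locus_ids(m$loci)[i],
            m$loci$ref[i], m$loci$alt[i], ".", "PASS",
            paste0("PC=", p), fmt, cells), collapse = "\t")
  }, "")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read dosages (and AD counts) from a VCF
#'
#' Multi-allelic records are excluded (with a count); the dosage is the
#' number of alternate alleles in the GT string, the ploidy context comes
#' from the INFO key `PC` or, failing that, the GT length.
#'
#' @param path VCF path.
#' @return a [dosage_matrix()]; when AD is present, attribute `counts`
#'   holds the matching [read_counts()].
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_param("package vcfR is required for VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  multi <- grepl(",", vcfR::getALT(v))
  if (any(multi)) {
    message(sum(multi), " multi-allelic record(s) excluded")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(vapply(gt, function(s) {
    if (is.na(s) || grepl("^\\.", s)) return(NA_integer_)
    sum(strsplit(s, "[/|]")[[1]] == "1")
  }, integer(1)), nrow(gt), dimnames = dimnames(gt))
  pc <- suppressWarnings(as.integer(vcfR::extract.info(v, "PC")))
  if (all(is.na(pc)))
    pc <- vapply(gt[, 1], function(s)
      length(strsplit(s, "[/|]")[[1]]), integer(1))
  fix <- vcfR::getFIX(v)
  loci <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     ploidy = as.integer(pc), stringsAsFactors = FALSE)
  out <- dosage_matrix(loci, dos)
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  if (!is.null(ad) && !all(is.na(ad))) {
    ref <- matrix(as.integer(sub(",.*", "", ad)), nrow(ad),
                  dimnames = dimnames(ad))
    alt <- matrix(as.integer(sub(".*,", "", ad)), nrow(ad),
                  dimnames = dimnames(ad))
    ref[is.na(ref)] <- 0L; alt[is.na(alt)] <- 0L
    attr(out, "counts") <- read_counts(loci, ref, alt)
  }
  out
}

# --- small TSV helpers ----------------------------------------------------

#' Read a sample-to-group labels TSV (`sample`, `group`)
#' @param path input path.
#' @return named character vector (sample -> group).
#' @export
read_groups_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read an admixture log-likelihood TSV (`K`, `run`, `logL`)
#' @param path input path.
#' @return data.frame.
#' @export
read_loglik_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read a Q-matrix TSV (first column sample id, remaining columns clusters)
#' @param path input path.
#' @return numeric matrix with sample rownames.
#' @export
read_qmatrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  q <- as.matrix(df[, -1, drop = FALSE])
  rownames(q) <- df[[1]]
  q
}
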