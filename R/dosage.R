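#' Assign the ploidy context of a locus from subgenome hits
#'
#' A hexaploid with two ancestral diploid subgenomes is genotyped against
#' both ancestral references: loci whose reads match both references are
#' genotyped at 6x, loci specific to subgenome A at 4x, loci specific to
#' subgenome B at 2x, and loci matching neither are unmapped (`NA`).
#'
#' @param hits_A,hits_B logical vectors: do the locus's reads match the A /
#'   B ancestral reference?
#' @return integer vector of ploidies (6, 4, 2) with `NA` for unmapped loci.
#' @export
assign_ploidy_context <- function(hits_A, hits_B) {
  n <- max(length(hits_A), length(hits_B))
  hits_A <- rep_len(as.logical(hits_A), n)
  hits_B <- rep_len(as.logical(hits_B), n)
  out <- rep(NA_integer_, n)
  out[hits_A & hits_B] <- 6L
  out[hits_A & !hits_B] <- 4L
  out[!hits_A & hits_B] <- 2L
  out
}

#' Caller configuration for allele-dosage genotyping
#'
#' @param error_rate assumed per-read allele error probability `e` in
#'   `[0, 0.5)`, used in the dosage likelihood.
#' @param uniform_depth_threshold minimum read depth for any call
#'   (default 45, the operational choice when dose classes are unknown a
#'   priori).
#' @param class_depth_thresholds optional named vector of per-genotype-class
#'   depth minima (names among `nulliplex`, `simplex`, `duplex`, `triplex`,
#'   `higher`); a provisional call's class selects its threshold and
#'   sub-threshold calls become missing. See [class_thresholds_95()].
#' @param tie_policy how likelihood ties break; only `"lower"` (smaller
#'   dosage wins) is implemented — ties essentially occur only at zero
#'   depth, which is already missing.
#' @return a `caller_config` list.
#' @export
caller_config <- function(error_rate = 0.001, uniform_depth_threshold = 45,
                          class_depth_thresholds = NULL,
                          tie_policy = "lower") {
  if (error_rate < 0 || error_rate >= 0.5)
    stop_param("error_rate must lie in [0, 0.5)")
  if (uniform_depth_threshold < 0) stop_param("thresholds must be >= 0")
  if (!is.null(class_depth_thresholds)) {
    if (is.null(names(class_depth_thresholds)) ||
        !all(names(class_depth_thresholds) %in% GENOTYPE_CLASSES))
      stop_param("class_depth_thresholds must be named by genotype class")
    if (any(class_depth_thresholds < 0)) stop_param("thresholds must be >= 0")
  }
  tie_policy <- match.arg(tie_policy, "lower")
  structure(list(error_rate = error_rate,
                 uniform_depth_threshold = uniform_depth_threshold,
                 class_depth_thresholds = class_depth_thresholds,
                 tie_policy = tie_policy),
            class = "caller_config")
}

#' Per-class depth thresholds at the 95% stability level
#'
#' The preset derived from the resampling diagnostic on hexaploid data:
#' nulliplex calls are stable from 1 read, simplex calls need 35 reads,
#' duplex and triplex (multi-dose) calls need 100.
#'
#' @return named integer vector usable as `class_depth_thresholds`.
#' @export
class_thresholds_95 <- function() {
  c(nulliplex = 1L, simplex = 35L, duplex = 100L, triplex = 100L,
    higher = 100L)
}

#' Log-likelihood of each allele dosage given ref/alt read counts
#'
#' Under the binomial dose model a read from a genotype with `d` alternate
#' alleles out of ploidy `p` reports the alternate allele with probability
#' `f(d) = (d/p)(1-e) + (1-d/p)e`; the log-likelihood of dosage `d` is
#' `alt*log f(d) + ref*log(1-f(d))` up to a shared constant. `-Inf` marks
#' dosages contradicted by the reads when `e = 0`.
#'
#' @param ref_reads,alt_reads non-negative read counts.
#' @param ploidy locus ploidy (2, 4 or 6).
#' @param error per-read allele error probability in `[0, 0.5)`.
#' @return numeric vector of `ploidy + 1` log-likelihoods (dosage 0..p).
#' @export
dosage_log_likelihood <- function(ref_reads, alt_reads, ploidy = 6,
                                  error = 0.001) {
  if (ref_reads < 0 || alt_reads < 0) stop_param("read counts must be >= 0")
  if (error < 0 || error >= 0.5) stop_param("error must lie in [0, 0.5)")
  d <- 0:ploidy
  f <- (d / ploidy) * (1 - error) + (1 - d / ploidy) * error
  ll_term(alt_reads, f) + ll_term(ref_reads, 1 - f)
}

# k * log(prob) with the 0 * log(0) = 0 convention; vectorized over both
ll_term <- function(k, prob) {
  n <- max(length(k), length(prob))
  k <- rep_len(k, n); prob <- rep_len(prob, n)
  out <- numeric(n)
  pos <- prob > 0
  out[pos] <- k[pos] * log(prob[pos])
  out[!pos & k > 0] <- -Inf
  out
}

# vectorized caller core: n cells at one ploidy -> integer dosages
call_cells <- function(ref, alt, ploidy, error) {
  n <- length(ref)
  d <- 0:ploidy
  f <- (d / ploidy) * (1 - error) + (1 - d / ploidy) * error
  ll <- matrix(0, n, ploidy + 1L)
  for (j in seq_along(d)) {
    ll[, j] <- ll_term(alt, f[j]) + ll_term(ref, 1 - f[j])
  }
  # ties.method = "first" realizes the break-toward-smaller-dosage policy
  as.integer(max.col(ll, ties.method = "first") - 1L)
}

#' Call allele dosages from a read-count table
#'
#' Maximum-likelihood dosage per cell under the locus's ploidy context.
#' Cells below the applicable depth threshold are missing: either the
#' uniform threshold, or — when `class_depth_thresholds` is set — the
#' threshold of the provisional call's genotype class. Zero-depth cells are
#' always missing.
#'
#' @param table a [read_counts()] object.
#' @param config a [caller_config()].
#' @return a [dosage_matrix()].
#' @export
call_dosages <- function(table, config = caller_config()) {
  stopifnot(inherits(table, "read_counts"), inherits(config, "caller_config"))
  depth <- table$ref + table$alt
  dosages <- matrix(NA_integer_, nrow(table$ref), ncol(table$ref),
                    dimnames = dimnames(table$ref))
  for (p in unique(table$loci$ploidy)) {
    rows <- which(table$loci$ploidy == p)
    idx <- which(depth[rows, , drop = FALSE] > 0)
    if (!length(idx)) next
    sub_ref <- table$ref[rows, , drop = FALSE][idx]
    sub_alt <- table$alt[rows, , drop = FALSE][idx]
    calls <- call_cells(sub_ref, sub_alt, p, config$error_rate)
    m <- matrix(NA_integer_, length(rows), ncol(dosages))
    m[idx] <- calls
    dosages[rows, ] <- m
  }
  # depth gating
  if (is.null(config$class_depth_thresholds)) {
    dosages[depth < config$uniform_depth_threshold] <- NA_integer_
  } else {
    thr <- config$class_depth_thresholds
    cls <- matrix(genotype_class(as.vector(dosages),
                                 rep(table$loci$ploidy, ncol(dosages))),
                  nrow(dosages), ncol(dosages))
    need <- matrix(thr[cls], nrow(dosages), ncol(dosages))
    dosages[!is.na(need) & depth < need] <- NA_integer_
  }
  dosages[depth == 0L] <- NA_integer_
  dosage_matrix(table$loci, dosages)
}

#' Genotype class of a dosage
#'
#' Classes are named by the minority-allele copy number
#' `m = min(d, p - d)`: nulliplex (0), simplex (1), duplex (2), triplex (3),
#' `higher` beyond (only possible above hexaploid).
#'
#' @param d integer dosages (NA allowed).
#' @param p ploidies, recycled against `d`.
#' @return character vector of class names (`NA` where `d` is missing).
#' @export
genotype_class <- function(d, p = 6) {
  n <- max(length(d), length(p))
  d <- rep_len(d, n); p <- rep_len(p, n)
  if (any(d > p, na.rm = TRUE) || any(d < 0, na.rm = TRUE))
    stop_param("dosage must lie in 0..ploidy")
  m <- pmin(d, p - d)
  out <- rep(NA_character_, n)
  out[!is.na(m)] <- ifelse(m[!is.na(m)] <= 3,
                           GENOTYPE_CLASSES[m[!is.na(m)] + 1L], "higher")
  out
}

#' Collapse polyploid dosages to diploidized codes
#'
#' 0 stays 0, full dosage (`d = p`) becomes 2, any intermediate dose becomes
#' 1, missing stays missing. This diploid-style coding is what the
#' diversity and structure statistics consume.
#'
#' @param m a [dosage_matrix()].
#' @return a [diplo_matrix()].
#' @export
diploidize <- function(m) {
  stopifnot(inherits(m, "dosage_matrix"))
  p <- m$loci$ploidy
  codes <- m$dosages
  full <- sweep(codes, 1, p, "==")
  full[is.na(full)] <- FALSE
  codes[!is.na(codes) & codes > 0L] <- 1L
  codes[full] <- 2L
  diplo_matrix(m$loci, codes)
}

# per-locus alt-allele frequency + missingness of a genotype matrix
locus_stats <- function(x, freq_from = c("codes", "dosage")) {
  freq_from <- match.arg(freq_from)
  if (inherits(x, "diplo_matrix")) {
    g <- x$codes; denom_per_sample <- rep(2, nrow(g))
  } else if (inherits(x, "dosage_matrix")) {
    g <- x$dosages
    denom_per_sample <- if (freq_from == "codes") rep(2, nrow(g)) else
      x$loci$ploidy
    if (freq_from == "codes") {
      g <- diploidize(x)$codes
    }
  } else stop_param("expected a dosage_matrix or diplo_matrix")
  n_called <- rowSums(!is.na(g))
  freq <- rowSums(g, na.rm = TRUE) / (denom_per_sample * pmax(n_called, 1L))
  freq[n_called == 0L] <- NA_real_
  data.frame(locus = locus_ids(x$loci),
             freq = freq,
             maf = pmin(freq, 1 - freq),
             missing = 1 - n_called / ncol(g),
             stringsAsFactors = FALSE)
}

#' Filter variants on minor allele frequency and missingness
#'
#' Retains loci with `MAF >= maf_min` and a missing-genotype fraction
#' `<= max_missing` (defaults 0.05 and 20%). MAF is computed from
#' diploidized codes (`sum(codes) / (2 n_called)`) by default; dosage-based
#' frequency (`sum(d) / (p n_called)`) is available via `freq_from`.
#' The operation is idempotent.
#'
#' @param m a [diplo_matrix()] or [dosage_matrix()].
#' @param maf_min minimum minor allele frequency (in `[0, 0.5]`).
#' @param max_missing maximum missing fraction (in `[0, 1]`).
#' @param freq_from `"codes"` (diploidized) or `"dosage"`.
#' @return the filtered matrix (same class), with attribute `report`: a
#'   per-locus data.frame stating which rule removed each dropped locus.
#' @export
filter_variants <- function(m, maf_min = 0.05, max_missing = 0.20,
                            freq_from = c("codes", "dosage")) {
  if (maf_min < 0 || maf_min > 0.5) stop_param("maf_min must lie in [0, 0.5]")
  if (max_missing < 0 || max_missing > 1)
    stop_param("max_missing must lie in [0, 1]")
  st <- locus_stats(m, freq_from)
  low_maf <- is.na(st$maf) | st$maf < maf_min
  too_missing <- st$missing > max_missing
  keep <- !low_maf & !too_missing
  reason <- rep("retained", nrow(st))
  reason[too_missing] <- "missingness"
  reason[low_maf] <- "maf"
  reason[low_maf & too_missing] <- "maf+missingness"
  report <- cbind(st, retained = keep, reason = reason)
  if (!any(keep)) warning("no loci survive filtering", call. = FALSE)
  out <- if (inherits(m, "diplo_matrix")) {
    diplo_matrix(m$loci[keep, , drop = FALSE], m$codes[keep, , drop = FALSE])
  } else {
    dosage_matrix(m$loci[keep, , drop = FALSE],
                  m$dosages[keep, , drop = FALSE])
  }
  attr(out, "report") <- report
  out
}
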