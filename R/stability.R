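#' Default read-resampling fraction grid
#'
#' 0.1% to 0.9% in steps of 0.1%, then 1% to 100% in steps of 1% — 109
#' fractions emulating many sequencing passes at increasing depth.
#'
#' @return numeric vector of 109 strictly increasing fractions in (0, 1].
#' @export
default_grid <- function() {
  g <- c(seq(0.001, 0.009, by = 0.001), seq(0.01, 1, by = 0.01))
  round(g, 3)
}

# multivariate hypergeometric draw: retain k of the reads described by the
# integer count vector `counts`, uniformly without replacement
mv_hypergeom <- function(counts, k) {
  total <- sum(counts)
  out <- integer(length(counts))
  rem_total <- total; rem_k <- k
  for (i in seq_along(counts)) {
    if (rem_k == 0L) break
    x <- stats::rhyper(1, counts[i], rem_total - counts[i], rem_k)
    out[i] <- x
    rem_k <- rem_k - x
    rem_total <- rem_total - counts[i]
  }
  out
}

#' Subsample one sample's reads without replacement
#'
#' Exactly `round(fraction * total)` reads are retained, drawn uniformly
#' without replacement from the sample's whole read pool (all loci, both
#' alleles), so per-locus retained counts follow the multivariate
#' hypergeometric distribution — a faithful model of re-capturing a fraction
#' of the sample's total reads.
#'
#' @param ref,alt per-locus integer read counts of one sample.
#' @param fraction fraction of the total reads to retain, in `[0, 1]`.
#' @param seed optional integer seed.
#' @return list with subsampled `ref` and `alt` vectors.
#' @export
subsample_sample_counts <- function(ref, alt, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1) stop_param("fraction must lie in [0, 1]")
  stopifnot(length(ref) == length(alt))
  with_seed(seed, {
    pool <- c(ref, alt)
    k <- round(fraction * sum(pool))
    kept <- mv_hypergeom(as.integer(pool), as.integer(k))
    L <- length(ref)
    list(ref = kept[seq_len(L)], alt = kept[L + seq_len(L)])
  })
}

#' Subsample every sample of a read-count table
#'
#' Applies [subsample_sample_counts()] per sample with per-sample seeds
#' derived from `seed`.
#'
#' @param counts a [read_counts()] object.
#' @param fraction fraction of each sample's total reads to retain.
#' @param seed integer seed.
#' @return a [read_counts()] object of subsampled counts.
#' @export
subsample_counts <- function(counts, fraction, seed = NULL) {
  stopifnot(inherits(counts, "read_counts"))
  ref <- counts$ref; alt <- counts$alt
  for (j in seq_len(ncol(ref))) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, paste0("sub", j))
    kept <- subsample_sample_counts(counts$ref[, j], counts$alt[, j],
                                    fraction, s)
    ref[, j] <- kept$ref; alt[, j] <- kept$alt
  }
  read_counts(counts$loci, ref, alt)
}

# integer depth bins 1..50, then geometric bins up to max_depth
make_depth_bins <- function(max_depth, ratio = 1.3) {
  lows <- 1:min(50L, max_depth)
  if (max_depth > 50L) {
    x <- 51
    while (x <= max_depth) {
      lows <- c(lows, as.integer(round(x)))
      x <- x * ratio
    }
    lows <- unique(lows)
  }
  highs <- c(lows[-1] - 1L, max(max_depth, lows[length(lows)]))
  data.frame(low = lows, high = highs)
}

#' Genotype stability curves from read resampling
#'
#' The empirical depth diagnostic: reference genotypes are called on the
#' full-depth counts (no depth threshold — low-depth instability is the
#' quantity being measured), then for every fraction of the grid each
#' sample's read pool is subsampled without replacement and genotypes are
#' re-called. Every (locus, sample, fraction) observation contributes its
#' realized depth and agreement with the full-depth call to the depth bin of
#' its full-depth genotype class; concordance is the per-bin agreement
#' fraction.
#'
#' @param counts a [read_counts()] table of designated high-depth samples.
#' @param caller a [caller_config()]; only its `error_rate` is used (depth
#'   thresholds are deliberately not applied inside the diagnostic).
#' @param grid fraction grid, default [default_grid()].
#' @param depth_bins optional data.frame (`low`, `high`); default integer
#'   bins to depth 50 then geometric bins.
#' @param seed integer seed.
#' @return a `stability_curve` data.frame: `class`, `bin_low`, `bin_high`,
#'   `n`, `concordance`.
#' @export
stability_curves <- function(counts, caller = caller_config(), grid = default_grid(),
                             depth_bins = NULL, seed = 1) {
  stopifnot(inherits(counts, "read_counts"))
  if (is.unsorted(grid, strictly = TRUE) || any(grid <= 0) || any(grid > 1))
    stop_param("grid fractions must be strictly increasing within (0, 1]")
  nothr <- caller_config(error_rate = caller$error_rate,
                         uniform_depth_threshold = 0)
  ref_calls <- call_dosages(counts, nothr)$dosages
  ref_class <- matrix(genotype_class(as.vector(ref_calls),
                                     rep(counts$loci$ploidy, ncol(ref_calls))),
                      nrow(ref_calls), ncol(ref_calls))
  max_depth <- max(counts$ref + counts$alt)
  if (is.null(depth_bins)) depth_bins <- make_depth_bins(max_depth)
  classes_present <- sort(unique(stats::na.omit(as.vector(ref_class))))
  absent <- setdiff(GENOTYPE_CLASSES[1:4], classes_present)
  if (length(absent))
    message("class(es) absent from the data: ", paste(absent, collapse = ", "))

  nb <- nrow(depth_bins)
  key_levels <- as.vector(outer(seq_len(nb), classes_present,
                                function(b, k) paste(k, b)))
  n_obs <- agree_n <- structure(numeric(length(key_levels)),
                                names = key_levels)
  valid_cell <- !is.na(ref_calls)
  for (fi in seq_along(grid)) {
    f <- grid[fi]
    sub <- subsample_counts(counts, f,
                            derive_seed(seed, paste0("frac", fi)))
    sub_calls <- call_dosages(sub, nothr)$dosages
    depth <- sub$ref + sub$alt
    use <- valid_cell & depth >= 1L
    if (!any(use)) next
    b <- findInterval(depth[use], c(depth_bins$low, Inf))
    key <- paste(ref_class[use], b)
    agree <- as.numeric(sub_calls[use] == ref_calls[use])
    tab_n <- tapply(rep(1, length(key)), key, sum)
    tab_a <- tapply(agree, key, sum)
    n_obs[names(tab_n)] <- n_obs[names(tab_n)] + tab_n
    agree_n[names(tab_a)] <- agree_n[names(tab_a)] + tab_a
  }
  parts <- strsplit(names(n_obs), " ")
  out <- data.frame(
    class = vapply(parts, `[`, "", 1),
    bin = as.integer(vapply(parts, `[`, "", 2)),
    n = as.vector(n_obs),
    agree = as.vector(agree_n), stringsAsFactors = FALSE)
  out <- out[out$n > 0, , drop = FALSE]
  out$bin_low <- depth_bins$low[out$bin]
  out$bin_high <- depth_bins$high[out$bin]
  out$concordance <- out$agree / out$n
  out <- out[order(match(out$class, GENOTYPE_CLASSES), out$bin_low),
             c("class", "bin_low", "bin_high", "n", "concordance")]
  rownames(out) <- NULL
  class(out) <- c("stability_curve", "data.frame")
  out
}

#' Read-depth thresholds per genotype class at a confidence level
#'
#' For each genotype class, the smallest bin lower-edge depth at which
#' concordance reaches `confidence` *and stays there* for every deeper
#' observed bin — a transient crossing of a noisy curve does not define the
#' threshold. Bins with fewer than `min_obs` observations are skipped rather
#' than treated as failures. When no depth qualifies, `achieved` is `FALSE`
#' and the maximum observed depth is reported.
#'
#' @param curve a [stability_curves()] result.
#' @param confidence required concordance, in (0, 1].
#' @param min_obs minimum observations for a bin to count.
#' @return a `threshold_table` data.frame: `class`, `confidence`,
#'   `threshold`, `achieved`, `max_depth_seen`.
#' @export
depth_thresholds <- function(curve, confidence = 0.95, min_obs = 30) {
  if (confidence <= 0 || confidence > 1)
    stop_param("confidence must lie in (0, 1]")
  out <- lapply(split(curve, curve$class), function(cc) {
    cc <- cc[cc$n >= min_obs, , drop = FALSE]
    cc <- cc[order(cc$bin_low), , drop = FALSE]
    thr <- NA_integer_; achieved <- FALSE
    if (nrow(cc)) {
      ok <- cc$concordance >= confidence
      # smallest bin from which all deeper observed bins also qualify
      stable_from <- rev(cumprod(rev(ok))) == 1
      if (any(stable_from)) {
        thr <- cc$bin_low[which(stable_from)[1]]
        achieved <- TRUE
      }
    }
    data.frame(class = cc$class[1] %||% NA_character_,
               confidence = confidence, threshold = thr,
               achieved = achieved,
               max_depth_seen = if (nrow(cc)) max(cc$bin_high) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$class <- rownames(out) <- NULL
  out$class <- names(split(curve, curve$class))
  out <- out[order(match(out$class, GENOTYPE_CLASSES)),
             c("class", "confidence", "threshold", "achieved",
               "max_depth_seen")]
  rownames(out) <- NULL
  class(out) <- c("threshold_table", "data.frame")
  out
}
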