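# --- EM haplotype-frequency machinery -------------------------------------
#
# Unphased two-locus genotype data determine all haplotype counts except for
# double heterozygotes, which are split between the coupling (11/00) and
# repulsion (10/01) phases. The EM iterates the expected split; allele
# frequencies are fully observed, so only D is effectively estimated.
#
# Tables are 3x3 genotype counts n[g1, g2] flattened column-major into 9-row
# matrices so many pairs run in one vectorized EM.

em_haplotypes <- function(tab9, tol = 1e-10, max_iter = 1000) {
  tab9 <- as.matrix(tab9)
  n <- function(a, b) tab9[a * 3 + b + 1, ]          # n[g1 = a, g2 = b]
  Tt <- 2 * colSums(tab9)
  c11 <- 2 * n(2, 2) + n(1, 2) + n(2, 1)
  c10 <- 2 * n(2, 0) + n(2, 1) + n(1, 0)
  c01 <- 2 * n(0, 2) + n(1, 2) + n(0, 1)
  c00 <- 2 * n(0, 0) + n(0, 1) + n(1, 0)
  dh <- n(1, 1)
  pA <- (c11 + c10 + dh) / Tt
  pB <- (c11 + c01 + dh) / Tt
  # linkage-equilibrium start
  h11 <- pA * pB; h10 <- pA * (1 - pB); h01 <- (1 - pA) * pB
  h00 <- (1 - pA) * (1 - pB)
  for (it in seq_len(max_iter)) {
    denom <- h11 * h00 + h10 * h01
    p_coupling <- ifelse(denom > 0, h11 * h00 / denom, 0.5)
    h11n <- (c11 + dh * p_coupling) / Tt
    h00n <- (c00 + dh * p_coupling) / Tt
    h10n <- (c10 + dh * (1 - p_coupling)) / Tt
    h01n <- (c01 + dh * (1 - p_coupling)) / Tt
    delta <- pmax(abs(h11n - h11), abs(h10n - h10),
                  abs(h01n - h01), abs(h00n - h00))
    h11 <- h11n; h10 <- h10n; h01 <- h01n; h00 <- h00n
    if (max(delta) < tol) break
  }
  pA <- h11 + h10; pB <- h11 + h01
  D <- h11 - pA * pB
  den <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- ifelse(den > 0, D^2 / den, NA_real_)
  list(h11 = h11, h10 = h10, h01 = h01, h00 = h00,
       pA = pA, pB = pB, D = D, r2 = pmin(pmax(r2, 0), 1))
}

# 3x3 table for one pair of code vectors over jointly called samples
pair_table <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  tab <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
  matrix(as.numeric(tab), 9, 1)
}

#' EM-based linkage-disequilibrium r-squared for one locus pair
#'
#' Two-locus haplotype frequencies are estimated from the unphased 3x3
#' genotype table by expectation-maximization (double heterozygotes split
#' fractionally between phases; linkage-equilibrium start; convergence when
#' haplotype frequencies change by less than 1e-10, at most 1000
#' iterations), and `r2 = D^2 / (pA pa pB pb)` with `D = p11 - pA pB`.
#'
#' @param g1,g2 diploidized code vectors (0/1/2, NA allowed) over the same
#'   samples; both loci must be polymorphic among jointly called samples.
#' @return list with `r2`, `D`, haplotype frequencies `h11`, `h10`, `h01`,
#'   `h00`, allele frequencies `pA`, `pB` and `n` (jointly called samples).
#' @export
ld_r2_em <- function(g1, g2) {
  tab <- pair_table(g1, g2)
  n <- sum(tab)
  pA <- (2 * sum(tab[c(7, 8, 9)]) + sum(tab[c(4, 5, 6)])) / (2 * n)
  pB <- (2 * sum(tab[c(3, 6, 9)]) + sum(tab[c(2, 5, 8)])) / (2 * n)
  if (n == 0 || pA %in% c(0, 1) || pB %in% c(0, 1))
    stop_param("r2 undefined: a locus is monomorphic among jointly called samples")
  est <- em_haplotypes(tab)
  c(lapply(est, as.numeric), list(n = n))
}

# r2 for all pairs among a set of loci (columns of `sub`: samples x loci),
# via 9 indicator cross-products; returns an L x L matrix (NA: monomorphic)
r2_matrix <- function(sub) {
  L <- ncol(sub)
  called <- !is.na(sub)
  ind <- lapply(0:2, function(v) {
    x <- called & sub == v
    x[is.na(x)] <- FALSE
    storage.mode(x) <- "numeric"
    x
  })
  tabs <- matrix(0, 9, L * L)
  for (a in 0:2) for (b in 0:2)
    tabs[a * 3 + b + 1, ] <- as.vector(crossprod(ind[[a + 1]], ind[[b + 1]]))
  est <- em_haplotypes(tabs)
  matrix(est$r2, L, L)
}

#' Prune markers by windowed linkage disequilibrium
#'
#' Sliding window of `window` retained markers advanced by `step` markers,
#' per chromosome in position order. Within a window, every pair with EM
#' `r2 > r2_max` triggers removal of the later (by position) marker; removed
#' markers never re-enter.
#'
#' @param m a [diplo_matrix()] with loci ordered by chromosome and position.
#' @param r2_max maximum tolerated r-squared (default 0.5).
#' @param window window size in retained markers (default 50).
#' @param step window increment (default 5).
#' @return list with `retained` (locus ids), `retained_index` (row indices
#'   into `m`), `matrix` (the pruned [diplo_matrix()]) and `n_removed`.
#' @export
ld_prune <- function(m, r2_max = 0.5, window = 50, step = 5) {
  stopifnot(inherits(m, "diplo_matrix"))
  keep <- rep(TRUE, nrow(m$codes))
  for (ch in unique(m$loci$chrom)) {
    rows <- which(m$loci$chrom == ch)
    rows <- rows[order(m$loci$pos[rows])]
    retained <- rep(TRUE, length(rows))
    start <- 1L
    repeat {
      ret <- which(retained)
      if (start > length(ret) - 1L) break
      win <- ret[seq.int(start, min(start + window - 1L, length(ret)))]
      if (length(win) >= 2) {
        r2 <- r2_matrix(t(m$codes[rows[win], , drop = FALSE]))
        alive <- rep(TRUE, length(win))
        for (a in seq_len(length(win) - 1)) {
          if (!alive[a]) next
          for (b in seq.int(a + 1, length(win))) {
            if (!alive[b]) next
            if (!is.na(r2[a, b]) && r2[a, b] > r2_max) alive[b] <- FALSE
          }
        }
        retained[win[!alive]] <- FALSE
      }
      start <- start + step
    }
    keep[rows[!retained]] <- FALSE
  }
  list(retained = locus_ids(m$loci)[keep],
       retained_index = which(keep),
       matrix = diplo_matrix(m$loci[keep, , drop = FALSE],
                             m$codes[keep, , drop = FALSE]),
       n_removed = sum(!keep))
}

#' Linkage-disequilibrium decay with distance
#'
#' EM r-squared for all intra-chromosomal marker pairs within
#' `max_distance`, aggregated in log-spaced distance bins; for each r2
#' threshold the crossing distance is where the binned mean first falls
#' below the threshold and stays below, linearly interpolated between bin
#' centers.
#'
#' @param m a [diplo_matrix()] with `chrom`/`pos` locus metadata.
#' @param thresholds r2 thresholds for crossing distances (default 0.1 and
#'   0.2).
#' @param max_distance maximum pair distance in bp (default 1e6).
#' @param n_bins number of log-spaced distance bins.
#' @return list with `pairs` (distance + r2 per pair), `curve` (bin centers
#'   and mean r2) and `crossings` (threshold, distance).
#' @export
ld_decay <- function(m, thresholds = c(0.1, 0.2), max_distance = 1e6,
                     n_bins = 25) {
  stopifnot(inherits(m, "diplo_matrix"))
  pairs <- NULL
  for (ch in unique(m$loci$chrom)) {
    rows <- which(m$loci$chrom == ch)
    if (length(rows) < 2) next
    rows <- rows[order(m$loci$pos[rows])]
    r2 <- r2_matrix(t(m$codes[rows, , drop = FALSE]))
    idx <- which(upper.tri(r2), arr.ind = TRUE)
    d <- abs(m$loci$pos[rows][idx[, 2]] - m$loci$pos[rows][idx[, 1]])
    ok <- d <= max_distance & !is.na(r2[idx])
    if (any(ok))
      pairs <- rbind(pairs, data.frame(
        chrom = ch,
        pos1 = m$loci$pos[rows][idx[ok, 1]],
        pos2 = m$loci$pos[rows][idx[ok, 2]],
        distance = d[ok], r2 = r2[idx][ok], stringsAsFactors = FALSE))
  }
  if (is.null(pairs) || !nrow(pairs))
    stop_param("no intra-chromosomal pairs within max_distance")
  breaks <- exp(seq(log(max(min(pairs$distance), 1)),
                    log(max(pairs$distance)), length.out = n_bins + 1))
  breaks[1] <- breaks[1] - 1e-9; breaks[n_bins + 1] <- breaks[n_bins + 1] + 1e-9
  bin <- cut(pairs$distance, breaks, labels = FALSE)
  curve <- data.frame(
    center = exp((log(breaks[-1]) + log(breaks[-(n_bins + 1)])) / 2),
    mean_r2 = as.numeric(tapply(pairs$r2, factor(bin, levels = 1:n_bins),
                                mean)),
    n = as.numeric(table(factor(bin, levels = 1:n_bins))))
  curve <- curve[curve$n > 0, , drop = FALSE]
  crossings <- data.frame(threshold = thresholds,
                          distance = NA_real_)
  for (k in seq_along(thresholds)) {
    thr <- thresholds[k]
    below <- curve$mean_r2 < thr
    stays <- rev(cumprod(rev(below))) == 1
    if (any(stays)) {
      i <- which(stays)[1]
      if (i == 1) {
        crossings$distance[k] <- curve$center[1]
      } else {
        x0 <- curve$center[i - 1]; y0 <- curve$mean_r2[i - 1]
        x1 <- curve$center[i]; y1 <- curve$mean_r2[i]
        crossings$distance[k] <-
          if (y0 > y1) x0 + (y0 - thr) / (y0 - y1) * (x1 - x0) else x1
      }
    }
  }
  list(pairs = pairs, curve = curve, crossings = crossings)
}
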