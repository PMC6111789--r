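#' Pairwise Weir-Cockerham FST between groups
#'
#' For each pair of groups, the Weir & Cockerham (1984) theta estimator on
#' the diploidized genotypes: per-locus variance components a (between
#' populations), b (between individuals within populations) and c (within
#' individuals) are accumulated as a ratio of sums over loci,
#' `theta = sum(a) / sum(a + b + c)`. Negative multi-locus estimates are
#' reported as computed.
#'
#' @param m a [diplo_matrix()]; codes are treated as diploid genotypes
#'   (1 = heterozygous).
#' @param groups named character vector or (`sample`, `group`) data.frame.
#' @param estimator `"wc"` (Weir-Cockerham, default) or `"hudson"`
#'   (Hudson/Bhatia ratio-of-averages, for sensitivity checks).
#' @return symmetric numeric matrix over groups with an exactly zero
#'   diagonal.
#' @export
pairwise_fst <- function(m, groups, estimator = c("wc", "hudson")) {
  stopifnot(inherits(m, "diplo_matrix"))
  estimator <- match.arg(estimator)
  g <- normalize_groups(groups, sample_names(m))
  grp <- split(names(g), g)
  sizes <- vapply(grp, length, integer(1))
  if (any(sizes < 2))
    stop_param("group(s) with fewer than 2 samples: ",
               paste(names(grp)[sizes < 2], collapse = ", "))
  gn <- names(grp)
  out <- matrix(0, length(gn), length(gn), dimnames = list(gn, gn))
  if (length(gn) < 2) return(out)
  for (i in seq_len(length(gn) - 1)) for (j in (i + 1):length(gn)) {
    theta <- if (estimator == "wc")
      wc_theta(m$codes[, match(grp[[i]], sample_names(m)), drop = FALSE],
               m$codes[, match(grp[[j]], sample_names(m)), drop = FALSE])
    else
      hudson_fst(m$codes[, match(grp[[i]], sample_names(m)), drop = FALSE],
                 m$codes[, match(grp[[j]], sample_names(m)), drop = FALSE])
    out[i, j] <- out[j, i] <- theta
  }
  out
}

# Weir & Cockerham (1984) theta for two populations of diploid genotypes,
# ratio of sums over loci. g1, g2: loci x samples code matrices {0,1,2,NA}.
wc_theta <- function(g1, g2) {
  r <- 2
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  keep <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2
  g1 <- g1[keep, , drop = FALSE]; g2 <- g2[keep, , drop = FALSE]
  n1 <- n1[keep]; n2 <- n2[keep]
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  sum(a) / sum(a + b + cc)
}

# Hudson estimator (Bhatia et al. 2013 formulation), ratio of averages
hudson_fst <- function(g1, g2) {
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  keep <- n1 >= 2 & n2 >= 2
  g1 <- g1[keep, , drop = FALSE]; g2 <- g2[keep, , drop = FALSE]
  n1 <- 2 * n1[keep]; n2 <- 2 * n2[keep]
  p1 <- rowSums(g1, na.rm = TRUE) / n1
  p2 <- rowSums(g2, na.rm = TRUE) / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
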