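# shared fixture builders; everything is generated in code at test time

toy_loci <- function(n, ploidy = 6, chrom = "chr1", spacing = 1000L) {
  data.frame(chrom = chrom, pos = seq_len(n) * spacing, ref = "A", alt = "T",
             ploidy = as.integer(ploidy), stringsAsFactors = FALSE)
}

# diploid-coded matrix wrapper around a plain code matrix
as_diplo <- function(codes, ploidy = 2, positions = NULL) {
  loci <- toy_loci(nrow(codes), ploidy)
  if (!is.null(positions)) loci$pos <- as.integer(positions)
  if (is.null(colnames(codes)))
    colnames(codes) <- sprintf("S%03d", seq_len(ncol(codes)))
  diplo_matrix(loci, codes)
}

# simulated diploid genotypes for two or more populations (known structure)
sim_structured_codes <- function(n_loci, n_pops, fst, n_per_pop, seed) {
  fr <- draw_population_frequencies(n_loci, n_pops, fst, c(0.05, 0.5),
                                    seed = seed)
  dos <- simulate_dosages(fr$pop, n_per_pop, ploidy = 2, seed = seed + 1)
  list(dip = as_diplo(dos$dosages),
       groups = stats::setNames(dos$ancestry, colnames(dos$dosages)),
       freqs = fr)
}

# brute-force dosage log-likelihoods via dbinom (independent of the caller)
brute_force_loglik <- function(ref, alt, ploidy, e) {
  d <- 0:ploidy
  f <- (d / ploidy) * (1 - e) + (1 - d / ploidy) * e
  dbinom(alt, ref + alt, f, log = TRUE)
}

# exact P(ML call = d_true) when alt reads ~ Binomial(n, f(d_true))
exact_call_accuracy <- function(n, d_true, ploidy, e) {
  k <- 0:n
  ll <- matrix(0, n + 1, ploidy + 1)
  for (d in 0:ploidy) {
    f <- (d / ploidy) * (1 - e) + (1 - d / ploidy) * e
    t1 <- if (f > 0) k * log(f) else ifelse(k > 0, -Inf, 0)
    t2 <- if (f < 1) (n - k) * log(1 - f) else ifelse(n - k > 0, -Inf, 0)
    ll[, d + 1] <- t1 + t2
  }
  call <- max.col(ll, ties.method = "first") - 1L
  f_true <- (d_true / ploidy) * (1 - e) + (1 - d_true / ploidy) * e
  sum(dbinom(k[call == d_true], n, f_true))
}

# grid + golden-section ML oracle for two-locus haplotype frequencies:
# allele frequencies are fully observed, so only D is free
grid_ml_r2 <- function(tab9) {
  n <- matrix(tab9, 3, 3)                      # n[g1+1, g2+1]
  N <- sum(n)
  pA <- (2 * sum(n[3, ]) + sum(n[2, ])) / (2 * N)
  pB <- (2 * sum(n[, 3]) + sum(n[, 2])) / (2 * N)
  lo <- max(-pA * pB, -(1 - pA) * (1 - pB)) + 1e-12
  hi <- min(pA * (1 - pB), (1 - pA) * pB) - 1e-12
  loglik <- function(D) {
    h <- c(`00` = (1 - pA) * (1 - pB) + D, `01` = (1 - pA) * pB - D,
           `10` = pA * (1 - pB) - D, `11` = pA * pB + D)
    if (any(h < 0)) return(-Inf)
    P <- matrix(0, 3, 3)
    hap <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
    for (i in 1:4) for (j in 1:4) {
      g1 <- hap[i, 1] + hap[j, 1]; g2 <- hap[i, 2] + hap[j, 2]
      P[g1 + 1, g2 + 1] <- P[g1 + 1, g2 + 1] + h[i] * h[j]
    }
    sum(n[n > 0] * log(P[n > 0]))
  }
  if (hi <= lo) return(list(r2 = 0, D = 0))
  grid <- seq(lo, hi, length.out = 2001)
  vals <- vapply(grid, loglik, 0)
  i <- which.max(vals)
  bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
  opt <- stats::optimize(loglik, bracket, maximum = TRUE, tol = 1e-12)
  D <- opt$maximum
  den <- pA * (1 - pA) * pB * (1 - pB)
  list(r2 = if (den > 0) D^2 / den else NA_real_, D = D)
}

# random unrooted tree with strictly positive branch lengths (additive oracle)
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 2)
  ape::unroot(tr)
}
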