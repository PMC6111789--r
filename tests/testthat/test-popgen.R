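test_that("MAF summaries match hand counts", {
  codes <- rbind(c(0L, 0L, 1L, 2L),   # freq 3/8 = 0.375
                 rep(1L, 4),          # freq 0.5
                 rep(0L, 4))          # monomorphic, MAF 0
  dip <- as_diplo(codes)
  ms <- maf_summary(dip)
  expect_equal(ms$per_locus$Total, c(0.375, 0.5, 0))
  expect_equal(ms$summary$mean_maf[ms$summary$group == "Total"],
               mean(c(0.375, 0.5, 0)))
  # per-group frequencies respect the group split
  grp <- c(S001 = "west", S002 = "west", S003 = "east", S004 = "east")
  ms2 <- maf_summary(dip, grp)
  expect_equal(ms2$per_locus$west[1], 0)      # codes (0,0)
  expect_equal(ms2$per_locus$east[1], 0.25)   # codes (1,2) -> 3/4 -> MAF 0.25
  expect_error(maf_summary(dip, c(S999 = "x")), "not in the genotype")
})

test_that("p-distance matches hand computations and its invariants", {
  codes <- cbind(i = c(0L, 2L, 1L), j = c(0L, 0L, 1L), k = c(0L, 2L, 1L))
  d <- p_distance(as_diplo(codes))
  expect_equal(d["i", "j"], 2 / 6, tolerance = 1e-12)
  expect_equal(d["i", "k"], 0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # maximum distance between opposite homozygotes
  dmax <- p_distance(as_diplo(cbind(a = rep(0L, 5), b = rep(2L, 5))))
  expect_equal(dmax["a", "b"], 1)
  # appending identical loci to both samples never increases the distance
  codes2 <- rbind(codes, matrix(1L, 10, 3, dimnames = list(NULL, c("i", "j", "k"))))
  d2 <- p_distance(as_diplo(codes2))
  expect_lte(d2["i", "j"], d["i", "j"])
  # pairwise missing handling: loci missing in one sample are excluded
  codes3 <- cbind(x = c(0L, NA, 2L), y = c(2L, 1L, 2L))
  expect_equal(p_distance(as_diplo(codes3))["x", "y"], 2 / 4)
  expect_error(p_distance(as_diplo(cbind(x = c(NA, 0L), y = c(2L, NA)))),
               "jointly called")
})

test_that("neighbor joining is exact on 3 taxa and additive matrices", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  # closed form: a = (dAB + dAC - dBC)/2 etc.
  lens <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(lens[["A"]], (5 + 9 - 10) / 2)
  expect_equal(lens[["B"]], (5 + 10 - 9) / 2)
  expect_equal(lens[["C"]], (9 + 10 - 5) / 2)
  # additive matrices: topology and all path lengths recovered
  tr0 <- random_additive_tree(6, seed = 21)
  D0 <- ape::cophenetic.phylo(tr0)
  rec <- neighbor_joining(D0)
  expect_equal(ape::dist.topo(tr0, rec), 0, ignore_attr = TRUE)
  expect_lt(max(abs(ape::cophenetic.phylo(rec)[rownames(D0), colnames(D0)] -
                    D0)), 1e-9)
  # label-permutation invariance
  perm <- sample(rownames(D0))
  rec2 <- neighbor_joining(D0[perm, perm])
  expect_equal(ape::dist.topo(rec, rec2), 0, ignore_attr = TRUE)
  expect_error(neighbor_joining(D[1:2, 1:2]), "3 taxa")
})

test_that("bootstrap interior-branch support separates clear clusters", {
  s <- sim_structured_codes(200, 2, 0.4, 8, seed = 25)
  tr <- interior_branch_support(s$dip, n_boot = 200, collapse_below = 50,
                                seed = 26)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, colnames(s$dip$codes))
  # the branch separating the two simulated populations is near-certain
  pops <- split(names(s$groups), s$groups)
  part <- ape::prop.part(tr)
  labels <- attr(part, "labels")
  found <- any(vapply(part, function(p) {
    tips <- sort(labels[p])
    identical(tips, sort(pops[[1]])) || identical(tips, sort(pops[[2]]))
  }, logical(1)))
  expect_true(found)
  supports <- suppressWarnings(as.numeric(tr$node.label))
  expect_gte(max(supports, na.rm = TRUE), 95)
  # every surviving internal branch has support >= 50 (or is the root)
  expect_true(all(supports >= 50, na.rm = TRUE))
})

test_that("Weir-Cockerham FST has the right fixed points and symmetry", {
  # opposite fixation -> theta = 1
  codes <- cbind(matrix(0L, 100, 10), matrix(2L, 100, 10))
  colnames(codes) <- sprintf("S%03d", 1:20)
  grp <- stats::setNames(rep(c("a", "b"), each = 10), colnames(codes))
  fst <- pairwise_fst(as_diplo(codes), grp)
  expect_equal(fst["a", "b"], 1)
  expect_equal(fst, t(fst))
  expect_true(all(diag(fst) == 0))
  # one population split in two -> theta ~ 0
  s <- sim_structured_codes(1000, 1, 0.05, 100, seed = 30)
  half <- stats::setNames(rep(c("g1", "g2"), 50), names(s$groups))
  th0 <- pairwise_fst(s$dip, half)["g1", "g2"]
  expect_lt(abs(th0), 0.01)
  # permuted labels on structured data also average to ~ 0
  s2 <- sim_structured_codes(1000, 2, 0.1, 50, seed = 31)
  set.seed(32)
  perm <- stats::setNames(sample(s2$groups), names(s2$groups))
  expect_lt(abs(pairwise_fst(s2$dip, perm)[1, 2]), 0.01)
  expect_error(pairwise_fst(s$dip, stats::setNames(
    c("a", rep("b", 99)), names(s$groups))), "fewer than 2")
})

test_that("EM r2 matches phased counts, oracles and fixed points", {
  set.seed(33)
  g <- sample(0:2, 400, TRUE, c(0.25, 0.5, 0.25))
  expect_equal(ld_r2_em(g, g)$r2, 1, tolerance = 1e-9)
  # independent loci: near-zero r2
  h <- sample(0:2, 400, TRUE, c(0.25, 0.5, 0.25))
  expect_lt(ld_r2_em(g, h)$r2, 0.05)
  expect_error(ld_r2_em(g, rep(0L, 400)), "monomorphic")
  # without double heterozygotes the phase is unambiguous: EM equals the
  # directly counted haplotype r2
  hap1 <- rbinom(300, 1, 0.4); hap2 <- ifelse(runif(300) < 0.8, hap1,
                                              rbinom(300, 1, 0.4))
  h1a <- matrix(hap1, ncol = 2); h2a <- matrix(hap2, ncol = 2)
  g1 <- rowSums(h1a); g2 <- rowSums(h2a)
  keep <- !(g1 == 1 & g2 == 1)
  r2_em <- ld_r2_em(g1[keep], g2[keep])$r2
  hk1 <- as.vector(h1a[keep, ]); hk2 <- as.vector(h2a[keep, ])
  r2_phased <- stats::cor(hk1, hk2)^2
  expect_equal(r2_em, r2_phased, tolerance = 1e-9)
})

test_that("windowed LD pruning removes duplicated markers deterministically", {
  set.seed(35)
  base <- matrix(sample(0:2, 6 * 120, TRUE, c(0.3, 0.4, 0.3)), 6)
  base[2, ] <- base[1, ]      # markers 1-2 identical
  base[5, ] <- base[4, ]      # markers 4-5 identical
  dip <- as_diplo(base)
  pr <- ld_prune(dip, r2_max = 0.5, window = 50, step = 5)
  expect_equal(pr$retained_index, c(1, 3, 4, 6))
  expect_equal(pr$n_removed, 2)
  # mutually independent markers are all retained
  indep <- matrix(sample(0:2, 8 * 500, TRUE, c(0.25, 0.5, 0.25)), 8)
  pr2 <- ld_prune(as_diplo(indep), 0.5, 50, 5)
  expect_equal(pr2$n_removed, 0)
  # windows only see markers on the same chromosome
  loci <- toy_loci(6, 2)
  loci$chrom <- rep(c("chr1", "chr2"), each = 3)
  dup_across <- base
  dip3 <- diplo_matrix(loci, dup_across)
  pr3 <- ld_prune(dip3, 0.5, 50, 5)
  expect_true(all(c(1, 4) %in% pr3$retained_index))
})

test_that("LD decay crossings are ordered and near the analytic distance", {
  # Markov haplotype chain: allele correlation between markers decays as
  # exp(-d / lambda), so r2(d) ~ exp(-2 d / lambda) and the analytic
  # crossing distance for threshold t is -(lambda / 2) log(t)
  set.seed(36)
  n <- 500; lambda <- 4000
  n_markers <- 80
  pos <- sort(sample(30000, n_markers))
  sim_hap <- function() {
    x <- numeric(n_markers)
    x[1] <- rbinom(1, 1, 0.5)
    for (k in 2:n_markers) {
      keep <- (1 + exp(-(pos[k] - pos[k - 1]) / lambda)) / 2
      x[k] <- if (runif(1) < keep) x[k - 1] else 1 - x[k - 1]
    }
    x
  }
  haps <- t(vapply(seq_len(2 * n), function(i) sim_hap(), numeric(n_markers)))
  codes <- haps[1:n, ] + haps[n + 1:n, ]
  dip <- as_diplo(t(codes), positions = pos)
  dc <- ld_decay(dip, thresholds = c(0.1, 0.2), max_distance = 30000)
  expect_true(all(dc$pairs$r2 >= 0 & dc$pairs$r2 <= 1 + 1e-9))
  d01 <- dc$crossings$distance[dc$crossings$threshold == 0.1]
  d02 <- dc$crossings$distance[dc$crossings$threshold == 0.2]
  expect_lte(d02, d01)   # higher threshold crossed earlier
  expect_equal(d01, lambda / 2 * log(1 / 0.1), tolerance = 0.25)
  expect_equal(d02, lambda / 2 * log(1 / 0.2), tolerance = 0.25)
})

test_that("genotype PCA separates structure and is internally consistent", {
  s <- sim_structured_codes(2000, 2, 0.1, 100, seed = 40)
  pc <- pca_genotypes(s$dip, n_components = 5)
  expect_equal(ncol(pc$scores), 5)
  expect_true(all(diff(pc$var_explained) <= 1e-9))
  expect_true(all(pc$var_explained >= 0 & pc$var_explained <= 100))
  # orthogonal scores
  cp <- crossprod(pc$scores)
  off <- abs(cp[upper.tri(cp)]) / sqrt(diag(cp)[1] * diag(cp)[2])
  expect_true(all(off < 1e-6))
  # PC1 separates the two populations with no overlap
  sc1 <- split(pc$scores[, 1], s$groups[rownames(pc$scores)])
  expect_true(max(sc1[[1]]) < min(sc1[[2]]) ||
              max(sc1[[2]]) < min(sc1[[1]]))
  # duplicated samples land on identical scores
  codes <- s$dip$codes[, c(1, 1, 2, 3)]
  colnames(codes) <- c("a", "b", "c", "d")
  pc2 <- pca_genotypes(as_diplo(codes), 2)
  expect_equal(pc2$scores["a", ], pc2$scores["b", ], tolerance = 1e-9)
  expect_error(pca_genotypes(s$dip, n_components = 1e4), "n_components")
})

test_that("Evanno delta-K reproduces the direct formula", {
  tbl <- expand.grid(K = 1:4, run = 1:3)
  mu <- c(-500, -400, -390, -388)[tbl$K]
  tbl$logL <- mu + c(-5, 0, 5)[tbl$run]      # run sd exactly 5 at every K
  dk <- evanno_delta_k(tbl)
  expect_equal(dk$delta_k, c(NA, 18, 1.6, NA))
  expect_equal(dk$defined, c(FALSE, TRUE, TRUE, FALSE))
  # perfectly linear logL -> delta K 0 at interior K
  tbl2 <- expand.grid(K = 1:4, run = 1:3)
  tbl2$logL <- -100 * tbl2$K + c(-1, 0, 1)[tbl2$run]
  expect_equal(evanno_delta_k(tbl2)$delta_k[2:3], c(0, 0))
  # identical replicate runs -> undefined (sd 0)
  tbl3 <- expand.grid(K = 1:3, run = 1:2)
  tbl3$logL <- c(-10, -5, -4)[tbl3$K]
  expect_false(evanno_delta_k(tbl3)$defined[2])
  expect_error(evanno_delta_k(data.frame(K = 1:3, run = 1, logL = 1:3)),
               "2 replicate")
})

test_that("q-threshold cluster assignment counts everyone once", {
  q <- rbind(c(0.70, 0.10, 0.10, 0.10),
             c(0.25, 0.25, 0.25, 0.25),
             c(0.10, 0.80, 0.05, 0.05))
  res <- assign_clusters(q, threshold = 0.65)
  expect_equal(res$assignments$cluster, c("C1", "admixed", "C2"))
  expect_equal(sum(res$counts$n), 3)
  # 10-sample toy: exactly the rows with max q >= 0.65 are assigned
  set.seed(44)
  q10 <- rdiri <- t(vapply(1:10, function(i) {
    x <- rgamma(4, c(5, 1, 1, 1)[sample(4)]); x / sum(x)
  }, numeric(4)))
  res10 <- assign_clusters(q10, 0.65)
  expect_equal(sum(res10$assignments$cluster != "admixed"),
               sum(apply(q10, 1, max) >= 0.65))
  expect_warning(assign_clusters(q, threshold = 0.4), "largest wins")
  expect_error(assign_clusters(q * 0.9, 0.65), "sum to 1")
})
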