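test_that("ploidy context follows the dual-reference hit pattern", {
  expect_equal(assign_ploidy_context(TRUE, TRUE), 6L)
  expect_equal(assign_ploidy_context(TRUE, FALSE), 4L)
  expect_equal(assign_ploidy_context(FALSE, TRUE), 2L)
  expect_true(is.na(assign_ploidy_context(FALSE, FALSE)))
  expect_equal(assign_ploidy_context(c(TRUE, FALSE), c(TRUE, TRUE)),
               c(6L, 2L))
})

test_that("dosage log-likelihood matches its definition and symmetries", {
  # error-free all-ref reads: argmax at 0, the opposite homozygote excluded,
  # intermediate dosages penalized exactly by ref * log(1 - d/p)
  ll <- dosage_log_likelihood(10, 0, 6, 0)
  expect_equal(which.max(ll) - 1, 0)
  expect_equal(ll[7], -Inf)
  expect_equal(ll[1:6], 10 * log(1 - (0:5) / 6))
  # mixed reads at e = 0 contradict both homozygotes only
  ll2 <- dosage_log_likelihood(3, 2, 6, 0)
  expect_equal(is.infinite(ll2), c(TRUE, rep(FALSE, 5), TRUE))
  # ref/alt swap mirrors the dosage axis
  ll_a <- dosage_log_likelihood(30, 5, 6, 0.01)
  ll_b <- dosage_log_likelihood(5, 30, 6, 0.01)
  expect_equal(ll_a, rev(ll_b), tolerance = 1e-12)
  expect_equal(which.max(ll_a) - 1, 1)   # alt fraction 0.143 nearest f(1)
  expect_error(dosage_log_likelihood(-1, 5), "counts")
})

test_that("caller thresholds and missingness behave as specified", {
  loci <- toy_loci(3)
  ref <- matrix(c(0L, 44L, 100L), 3, 1)
  alt <- matrix(c(0L, 0L, 0L), 3, 1)
  rc <- read_counts(loci, ref, alt)
  dos <- call_dosages(rc, caller_config(error_rate = 0.001,
                                        uniform_depth_threshold = 45))
  expect_true(is.na(dos$dosages[1, 1]))   # zero depth
  expect_true(is.na(dos$dosages[2, 1]))   # 44 < 45
  expect_equal(dos$dosages[3, 1], 0L)
  # class-specific thresholds: a simplex-looking call needs 35 reads
  rc2 <- read_counts(toy_loci(2), matrix(c(25L, 50L), 2, 1),
                     matrix(c(5L, 10L), 2, 1))
  dos2 <- call_dosages(rc2, caller_config(
    error_rate = 0.001, class_depth_thresholds = class_thresholds_95()))
  expect_true(is.na(dos2$dosages[1, 1]))  # depth 30 < simplex threshold 35
  expect_equal(dos2$dosages[2, 1], 1L)    # depth 60 passes
})

test_that("high-depth error-free calls recover the simulated truth", {
  # the exact binomial computation puts the hardest class (triplex) above
  # 98% from ~200 reads and the average well above 99%; check the caller
  # realizes that on simulated cells of depth >= 200
  acc_exact <- vapply(0:6, function(d) exact_call_accuracy(250, d, 6, 0), 0)
  expect_gte(mean(acc_exact), 0.99)
  set.seed(42)
  dos_true <- matrix(sample(0:6, 10000, replace = TRUE), 100, 100)
  rc <- simulate_read_counts(dos_true, 300, 1e6, error_rate = 0, seed = 2)
  called <- call_dosages(rc, caller_config(error_rate = 0,
                                           uniform_depth_threshold = 200))
  ok <- !is.na(called$dosages)
  expect_gt(mean(ok), 0.5)
  expect_gte(mean(called$dosages[ok] == dos_true[ok]), 0.99)
})

test_that("caller accuracy grows with depth for every genotype class", {
  e <- 0.005
  acc <- vapply(c(10, 50, 200, 1000), function(n)
    vapply(0:3, function(d) exact_call_accuracy(n, d, 6, e), 0), numeric(4))
  # monotone non-decreasing in depth, per class (exact computation)
  for (cl in 1:4) expect_true(all(diff(acc[cl, ]) >= -1e-12))
  expect_true(all(acc[, 4] > 0.99))
})

test_that("dosage symmetry: swapping ref and alt mirrors every call", {
  set.seed(7)
  loci <- toy_loci(50)
  ref <- matrix(rpois(500, 60), 50, 10); alt <- matrix(rpois(500, 30), 50, 10)
  rc <- read_counts(loci, ref, alt)
  rc_sw <- read_counts(loci, alt, ref)
  cfg <- caller_config(error_rate = 0.01, uniform_depth_threshold = 1)
  a <- call_dosages(rc, cfg)$dosages
  b <- call_dosages(rc_sw, cfg)$dosages
  expect_equal(b, 6L - a)
})

test_that("genotype classes and diploidization are consistent", {
  expect_equal(genotype_class(c(0, 6), 6), c("nulliplex", "nulliplex"))
  expect_equal(genotype_class(c(1, 5), 6), c("simplex", "simplex"))
  expect_equal(genotype_class(c(2, 4), 6), c("duplex", "duplex"))
  expect_equal(genotype_class(3, 6), "triplex")
  expect_equal(genotype_class(2, 4), "duplex")
  expect_true(is.na(genotype_class(NA, 6)))
  expect_error(genotype_class(7, 6), "0..ploidy")

  d <- dosage_matrix(toy_loci(4),
                     matrix(c(0L, 3L, 6L, NA), 4, 1))
  dip <- diploidize(d)
  expect_equal(dip$codes[, 1], c(0L, 1L, 2L, NA), ignore_attr = TRUE)
  # code 1 iff class is simplex/duplex/triplex at p = 6
  dd <- dosage_matrix(toy_loci(7), matrix(0:6, 7, 1))
  cls <- genotype_class(0:6, 6)
  expect_equal(diploidize(dd)$codes[, 1] == 1L,
               cls %in% c("simplex", "duplex", "triplex"),
               ignore_attr = TRUE)
})

test_that("variant filtering applies both rules and is idempotent", {
  # 5 loci with MAFs (0, 0.04, 0.05, 0.30, 0.50) and missing
  # (0, 0, 0, 0.5, 0): survivors are loci 3 and 5
  codes <- rbind(rep(0L, 50),
                 c(rep(1L, 4), rep(0L, 46)),
                 c(rep(1L, 5), rep(0L, 45)),
                 c(rep(2L, 15), rep(0L, 10), rep(NA, 25)),
                 rep(1L, 50))
  dip <- as_diplo(codes)
  f <- filter_variants(dip, maf_min = 0.05, max_missing = 0.20)
  expect_equal(nrow(f$codes), 2)
  expect_equal(f$loci$pos, c(3000L, 5000L))
  rep_ <- attr(f, "report")
  expect_equal(rep_$reason, c("maf", "maf", "retained", "missingness",
                              "retained"))
  expect_equal(rep_$maf[1:3], c(0, 0.04, 0.05))
  # idempotence
  f2 <- filter_variants(f, maf_min = 0.05, max_missing = 0.20)
  expect_identical(f$codes, f2$codes)
  expect_warning(filter_variants(as_diplo(matrix(0L, 3, 10))), "no loci")
})
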