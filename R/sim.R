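#' Simulation configuration for synthetic hexaploid GBS data
#'
#' Bundles every knob of the generator: population structure (Balding-Nichols
#' differentiation `fst` across `n_pops` populations), cohort size, locus
#' count, ploidy, the read-depth model (negative binomial with `mean_depth`
#' and `depth_dispersion`), sequencing `error_rate`, the distribution of
#' subgenome-of-origin labels (reads matching both ancestral references give
#' 6x loci, reads specific to subgenome A give 4x, to subgenome B give 2x),
#' the ancestral minor-allele-frequency window and an optional Dirichlet
#' admixture parameter.
#'
#' The default `subgenome_probs` are the study-like read proportions
#' 85.7 : 3.1 : 7.2 (both : A-only : B-only), renormalized to sum to one
#' (the residual ~4% of real reads map to neither reference and carry no
#' genotype, so they are not simulated).
#'
#' @param n_pops number of populations.
#' @param fst Balding-Nichols differentiation parameter, in (0,1).
#' @param n_samples_per_pop samples per population.
#' @param n_loci number of biallelic loci.
#' @param ploidy even integer, default 6 (hexaploid).
#' @param mean_depth mean reads per locus per sample.
#' @param depth_dispersion negative-binomial size parameter; Poisson in the
#'   limit of large dispersion. Default 5 gives the broad empirical spread of
#'   GBS depths.
#' @param error_rate per-read probability that a read reports the wrong
#'   allele, in `[0, 0.5)`.
#' @param subgenome_probs probabilities of origin labels `both`, `A_only`,
#'   `B_only`; must sum to 1.
#' @param maf_range interval within (0, 0.5] for ancestral minor allele
#'   frequencies.
#' @param admixture_alpha positive Dirichlet concentration for per-sample
#'   admixture, or `NULL` for discrete population membership.
#' @param positions optional list of per-chromosome 1-based positions; by
#'   default all loci are placed on one chromosome at 1 kb spacing.
#' @param seed integer seed (mandatory).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pops = 2, fst = 0.05, n_samples_per_pop = 48,
                       n_loci = 1000, ploidy = 6, mean_depth = 60,
                       depth_dispersion = 5, error_rate = 0.001,
                       subgenome_probs = c(both = 0.857, A_only = 0.031,
                                           B_only = 0.072) / 0.96,
                       maf_range = c(0.05, 0.5), admixture_alpha = NULL,
                       positions = NULL, seed) {
  if (missing(seed)) stop_param("a seed is mandatory for simulation runs")
  if (!is_count(n_pops) || !is_count(n_samples_per_pop) || !is_count(n_loci))
    stop_param("n_pops, n_samples_per_pop and n_loci must be positive integers")
  if (!(fst > 0 && fst < 1)) stop_param("fst must lie in (0, 1)")
  if (!is_count(ploidy) || ploidy %% 2 != 0)
    stop_param("ploidy must be a positive even integer")
  if (mean_depth <= 0 || depth_dispersion <= 0)
    stop_param("mean_depth and depth_dispersion must be positive")
  if (error_rate < 0 || error_rate >= 0.5)
    stop_param("error_rate must lie in [0, 0.5): dosage identifiability is lost at 0.5")
  if (length(subgenome_probs) != 3 || any(subgenome_probs < 0) ||
      abs(sum(subgenome_probs) - 1) > 1e-12)
    stop_param("subgenome_probs must be three non-negative values summing to 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_param("maf_range must be an interval within (0, 0.5]")
  if (!is.null(admixture_alpha) && admixture_alpha <= 0)
    stop_param("admixture_alpha must be positive when supplied")
  names(subgenome_probs) <- c("both", "A_only", "B_only")
  structure(list(n_pops = as.integer(n_pops), fst = fst,
                 n_samples_per_pop = as.integer(n_samples_per_pop),
                 n_loci = as.integer(n_loci), ploidy = as.integer(ploidy),
                 mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 error_rate = error_rate, subgenome_probs = subgenome_probs,
                 maf_range = maf_range, admixture_alpha = admixture_alpha,
                 positions = positions, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw ancestral and per-population allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are uniform on `maf_range`, mirrored to `1 - q` with
#' probability one half so both alleles can be the minor one. Population
#' frequencies are Beta-distributed around each ancestral frequency with
#' parameters `q(1-F)/F` and `(1-q)(1-F)/F`, so their variance is
#' `q(1-q)F` and a Weir-Cockerham estimate on large samples recovers `F`.
#'
#' @param n_loci,n_pops dimensions.
#' @param fst differentiation parameter in (0,1).
#' @param maf_range ancestral minor-allele-frequency window within (0, 0.5].
#' @param seed integer seed.
#' @return list with `ancestral` (length `n_loci`) and `pop`
#'   (`n_loci` x `n_pops` matrix).
#' @export
draw_population_frequencies <- function(n_loci, n_pops, fst,
                                        maf_range = c(0.05, 0.5), seed = NULL) {
  if (!(fst > 0 && fst < 1)) stop_param("fst must lie in (0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] >= maf_range[2])
    stop_param("degenerate maf_range")
  with_seed(seed, {
    q <- runif(n_loci, maf_range[1], maf_range[2])
    flip <- runif(n_loci) < 0.5
    q[flip] <- 1 - q[flip]
    a <- q * (1 - fst) / fst
    b <- (1 - q) * (1 - fst) / fst
    pop <- matrix(rbeta(n_loci * n_pops, rep(a, n_pops), rep(b, n_pops)),
                  nrow = n_loci, ncol = n_pops)
    colnames(pop) <- paste0("pop", seq_len(n_pops))
    list(ancestral = q, pop = pop)
  })
}

# Dirichlet draws via normalized gammas
rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate allele dosages under polysomic Hardy-Weinberg proportions
#'
#' Each sample's dosage at a locus is Binomial(ploidy, q) with q its
#' population's (or, under admixture, its ancestry-weighted) allele
#' frequency — polysomic inheritance with independent allele draws.
#'
#' @param pop_freqs loci x populations frequency matrix (or vector for one
#'   population).
#' @param n_samples_per_pop samples drawn from each population.
#' @param ploidy scalar or per-locus vector of even ploidies.
#' @param admixture_alpha optional Dirichlet concentration; when given, each
#'   sample gets ancestry proportions over the populations and its effective
#'   frequency is the ancestry-weighted mix.
#' @param seed integer seed.
#' @return list with `dosages` (loci x samples integer matrix), `ancestry`
#'   (population labels, or the samples x populations proportion matrix under
#'   admixture) and `ploidy` (per-locus vector).
#' @export
simulate_dosages <- function(pop_freqs, n_samples_per_pop, ploidy = 6,
                             admixture_alpha = NULL, seed = NULL) {
  pop_freqs <- as.matrix(pop_freqs)
  if (any(pop_freqs < 0 | pop_freqs > 1))
    stop_param("frequencies must lie in [0, 1]")
  if (any(ploidy <= 0 | ploidy %% 2 != 0))
    stop_param("ploidy must be a positive even integer")
  n_loci <- nrow(pop_freqs); n_pops <- ncol(pop_freqs)
  p <- rep_len(as.integer(ploidy), n_loci)
  n_samples <- n_samples_per_pop * n_pops
  with_seed(seed, {
    if (is.null(admixture_alpha)) {
      pop_of <- rep(seq_len(n_pops), each = n_samples_per_pop)
      qs <- pop_freqs[, pop_of, drop = FALSE]       # loci x samples
      ancestry <- colnames(pop_freqs)[pop_of]
      if (is.null(ancestry)) ancestry <- paste0("pop", pop_of)
    } else {
      anc <- rdirichlet(n_samples, rep(admixture_alpha, n_pops))
      colnames(anc) <- colnames(pop_freqs)
      qs <- pop_freqs %*% t(anc)
      ancestry <- anc
    }
    d <- matrix(rbinom(n_loci * n_samples, rep(p, n_samples), as.vector(qs)),
                nrow = n_loci)
    colnames(d) <- sprintf("S%03d", seq_len(n_samples))
    storage.mode(d) <- "integer"
    list(dosages = d, ancestry = ancestry, ploidy = p)
  })
}

#' Simulate per-locus/per-sample read counts from true dosages
#'
#' Total depth is negative binomial (`mu = mean_depth`,
#' `size = depth_dispersion`). Given a true dosage `d` at ploidy `p`, a read
#' reports the alternate allele with probability
#' `f = (d/p)(1 - e) + (1 - d/p)e`, so alt reads are Binomial(depth, f).
#' The per-locus ploidy context is attached from the subgenome-of-origin
#' labels (`both` = 6x, `A_only` = 4x, `B_only` = 2x).
#'
#' @param dosages loci x samples integer matrix of true dosages.
#' @param mean_depth,depth_dispersion negative-binomial depth model.
#' @param error_rate per-read allele error probability, in `[0, 0.5)`.
#' @param subgenome_labels per-locus label in `both`, `A_only`, `B_only`;
#'   the implied ploidy must be able to carry the dosages.
#' @param seed integer seed.
#' @param positions optional locus data.frame (`chrom`, `pos`, `ref`, `alt`)
#'   overriding the default 1 kb grid.
#' @return a [read_counts()] object.
#' @export
simulate_read_counts <- function(dosages, mean_depth, depth_dispersion = 5,
                                 error_rate = 0, subgenome_labels = NULL,
                                 seed = NULL, positions = NULL) {
  dosages <- as.matrix(dosages)
  if (mean_depth <= 0) stop_param("mean_depth must be positive")
  if (error_rate < 0 || error_rate >= 0.5)
    stop_param("error_rate must lie in [0, 0.5)")
  n_loci <- nrow(dosages); n_samples <- ncol(dosages)
  if (is.null(subgenome_labels)) subgenome_labels <- rep("both", n_loci)
  if (!all(subgenome_labels %in% names(SUBGENOME_PLOIDY)))
    stop_param("subgenome labels must be both, A_only or B_only")
  p <- SUBGENOME_PLOIDY[subgenome_labels]
  if (any(dosages > p, na.rm = TRUE))
    stop_param("dosages exceed the ploidy implied by the subgenome labels")
  with_seed(seed, {
    depth <- matrix(rnbinom(n_loci * n_samples, mu = mean_depth,
                            size = depth_dispersion), nrow = n_loci)
    frac <- (dosages / p) * (1 - error_rate) +
            (1 - dosages / p) * error_rate
    alt <- matrix(rbinom(n_loci * n_samples, as.vector(depth), as.vector(frac)),
                  nrow = n_loci)
    ref <- depth - alt
    if (is.null(positions))
      positions <- data.frame(chrom = "chr1", pos = seq_len(n_loci) * 1000L,
                              ref = "A", alt = "T",
                              stringsAsFactors = FALSE)
    loci <- cbind(positions[, c("chrom", "pos", "ref", "alt")],
                  ploidy = as.integer(p),
                  subgenome = subgenome_labels)
    colnames(ref) <- colnames(alt) <-
      colnames(dosages) %||% sprintf("S%03d", seq_len(n_samples))
    read_counts(loci, ref, alt)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete synthetic GBS dataset with known truth
#'
#' Runs the generative chain: subgenome labels (hence per-locus ploidy
#' context), Balding-Nichols population frequencies, polysomic dosages and
#' negative-binomial read counts. Hexaploid dosages live on 6x loci; loci
#' specific to one subgenome are genotyped at 4x or 2x.
#'
#' @param config a [sim_config()].
#' @return list with `counts` ([read_counts()]) and `truth` (ancestral and
#'   population frequencies, true dosages, ancestry, subgenome labels,
#'   per-locus ploidy).
#' @export
simulate_gbs_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sg <- with_seed(derive_seed(config$seed, "subgenome"), {
    sample(names(SUBGENOME_PLOIDY), config$n_loci, replace = TRUE,
           prob = config$subgenome_probs)
  })
  # ploidy context: full ploidy at 'both' loci, scaled down on
  # subgenome-specific loci
  p <- as.integer(SUBGENOME_PLOIDY[sg] / 6 * config$ploidy)
  p <- pmax(p, 2L)
  freqs <- draw_population_frequencies(config$n_loci, config$n_pops,
                                       config$fst, config$maf_range,
                                       derive_seed(config$seed, "frequencies"))
  dos <- simulate_dosages(freqs$pop, config$n_samples_per_pop, p,
                          config$admixture_alpha,
                          derive_seed(config$seed, "dosages"))
  positions <- NULL
  if (!is.null(config$positions)) {
    positions <- do.call(rbind, lapply(names(config$positions), function(ch)
      data.frame(chrom = ch, pos = as.integer(config$positions[[ch]]),
                 ref = "A", alt = "T", stringsAsFactors = FALSE)))
    if (nrow(positions) != config$n_loci)
      stop_param("positions must supply exactly n_loci coordinates")
  }
  counts <- simulate_read_counts(dos$dosages, config$mean_depth,
                                 config$depth_dispersion, config$error_rate,
                                 sg, derive_seed(config$seed, "reads"),
                                 positions)
  truth <- list(ancestral_freqs = freqs$ancestral, pop_freqs = freqs$pop,
                true_dosages = dos$dosages, ancestry = dos$ancestry,
                subgenome_labels = sg, ploidy = p)
  list(counts = counts, truth = truth)
}

#' Simulate barcoded GBS FASTQ reads with a truth manifest
#'
#' Each read is an 8-bp buffer, a sample barcode (6-9 bp) and a random
#' genomic insert, with constant high base qualities and an optional
#' low-quality tail to exercise trimming. Barcode errors (substitution,
#' insertion or deletion, one per affected read) are injected at
#' `barcode_error_rate`.
#'
#' @param read_count_plan named integer vector: reads to emit per sample.
#'   Names must match the barcode set's sample ids.
#' @param barcode_set a [design_barcodes()] result (or data.frame with
#'   `sample_id`, `barcode`).
#' @param path FASTQ output path.
#' @param manifest_path truth manifest TSV path (`read_id`, `sample_id`).
#' @param buffer_sequence 8-bp constant buffer upstream of the barcode.
#' @param insert_length genomic insert length per read.
#' @param barcode_error_rate per-read probability of one barcode error.
#' @param base_quality constant Phred quality of emitted bases.
#' @param tail_length,tail_quality optional low-quality tail (last
#'   `tail_length` bases get `tail_quality`).
#' @param seed integer seed.
#' @return invisibly, the manifest data.frame.
#' @export
simulate_fastq <- function(read_count_plan, barcode_set, path, manifest_path,
                           buffer_sequence = "ACGTCTGA", insert_length = 64,
                           barcode_error_rate = 0, base_quality = 38,
                           tail_length = 0, tail_quality = 28, seed = NULL) {
  bc <- as.data.frame(barcode_set)
  if (anyDuplicated(bc$barcode)) stop_param("barcode set contains duplicates")
  if (nchar(buffer_sequence) != 8) stop_param("buffer must be 8 bp")
  if (any(nchar(bc$barcode) < 6 | nchar(bc$barcode) > 9))
    stop_param("barcode lengths must lie in 6-9")
  if (is.null(names(read_count_plan)))
    stop_param("read_count_plan must be named by sample id")
  missing_bc <- setdiff(names(read_count_plan), bc$sample_id)
  if (length(missing_bc))
    stop_param("no barcode for sample(s): ", paste(missing_bc, collapse = ", "))
  with_seed(seed, {
    sample_of <- rep(names(read_count_plan), read_count_plan)
    n <- length(sample_of)
    barcode_of <- bc$barcode[match(sample_of, bc$sample_id)]
    inserts <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), insert_length, replace = TRUE),
            collapse = ""), "")
    hit <- runif(n) < barcode_error_rate
    barcode_of[hit] <- vapply(barcode_of[hit], mutate_barcode, "")
    seqs <- paste0(buffer_sequence, barcode_of, inserts)
    quals <- vapply(nchar(seqs), function(L) {
      q <- rep(base_quality, L)
      if (tail_length > 0) q[seq.int(L - tail_length + 1, L)] <- tail_quality
      intToUtf8(q + 33L)
    }, "")
    ids <- sprintf("read%06d", seq_len(n))
    manifest <- data.frame(read_id = ids, sample_id = sample_of,
                           stringsAsFactors = FALSE)
    write_fastq(data.frame(id = ids, seq = seqs, qual = quals,
                           stringsAsFactors = FALSE), path)
    utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(manifest)
  })
}

# one random edit (substitution / insertion / deletion) inside a barcode
mutate_barcode <- function(b) {
  L <- nchar(b)
  type <- sample(c("sub", "ins", "del"), 1)
  pos <- sample(L, 1)
  chars <- strsplit(b, "")[[1]]
  if (type == "sub") {
    chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1)
  } else if (type == "ins") {
    chars <- append(chars, sample(c("A", "C", "G", "T"), 1), after = pos - 1)
  } else {
    chars <- chars[-pos]
  }
  paste(chars, collapse = "")
}
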