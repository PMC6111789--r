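---
title: "Methods: dosage genotyping and diversity statistics for hexaploid GBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage genotyping and diversity statistics for hexaploid GBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polygbs)
```

# Overview

`polygbs` implements a genotyping-by-sequencing (GBS) analysis chain for a
hexaploid crop with two ancestral diploid subgenomes — the situation of
cultivated sweetpotato (*Ipomoea batatas*, 2n = 6x = 90), whose purported
diploid ancestors are *I. trifida* and *I. triloba*. The chain runs from
barcoded reads to population-genetic summaries:

1. barcode design, buffer/quality trimming and edit-distance-tolerant
   demultiplexing;
2. per-locus ploidy-context assignment (6x/4x/2x) and maximum-likelihood
   allele-dosage calling from ref/alt read counts;
3. an empirical read-resampling diagnostic that measures genotype-call
   stability as a function of read depth and derives per-genotype-class
   depth thresholds;
4. variant filtering, and diversity/structure statistics on diploidized
   genotypes (MAF summaries, p-distance, neighbor-joining trees with
   bootstrap interior-branch support, Weir–Cockerham FST, EM-based LD
   r^2 with windowed pruning and decay curves, PCA, Evanno delta-K, and
   q-threshold cluster assignment).

Every stage is exercisable on the bundled synthetic-data generator, which
produces hexaploid dosage genotypes with known truth, so the whole pipeline
is testable without any external sequencing data.

# The dosage model

A locus in a polyploid of ploidy $p$ carries $d \in \{0, \dots, p\}$ copies
of the alternate allele. Under unbiased sampling of alleles by reads and a
symmetric per-read error rate $e$, a read reports the alternate allele with
probability

$$f(d) = \frac{d}{p}(1 - e) + \Big(1 - \frac{d}{p}\Big)e,$$

so, given $a$ alternate and $r$ reference reads, the dosage log-likelihood
is $\ell(d) = a \log f(d) + r \log(1 - f(d))$ up to a shared binomial
constant. The caller reports the maximizing $d$; ties break toward the
smaller dosage (ties only arise in degenerate cases such as zero depth,
which is already treated as missing). Note that with $e = 0$ only the
homozygote contradicted by the data is excluded outright ($-\infty$);
intermediate dosages always retain finite likelihood $r\log(1 - d/p)$.

**Ploidy context.** Reads from a locus are matched against both ancestral
references. Loci hitting both references are genotyped at 6x, loci specific
to subgenome A at 4x, and loci specific to subgenome B at 2x; loci hitting
neither are unmapped and excluded. Genotype classes are named by the
minority allele count $m = \min(d, p - d)$: nulliplex (0), simplex (1),
duplex (2), triplex (3).

**Depth thresholds.** Calls below a depth threshold become missing. The
default is a uniform 45-read threshold — the operational choice when dose
classes are unknown a priori. A per-class preset
(`class_thresholds_95()`: nulliplex 1, simplex 35, duplex/triplex 100)
applies each provisional call's class-specific threshold instead.

**Diploidization.** For diversity statistics the dosages are collapsed to
diploid-style codes: 0 (no alternate allele), 2 (all alleles alternate), 1
(any intermediate dose). MAF filtering and summaries compute the alternate
allele frequency from these codes as $\sum c / (2 n_\text{called})$; a
dosage-based frequency $\sum d / (p\, n_\text{called})$ is available as an
option (`freq_from = "dosage"`). Filtering keeps loci with MAF $\ge$ 0.05
and missingness $\le$ 20% by default.

# The read-resampling stability diagnostic

The optimal depth for calling each genotype class is determined
empirically, not assumed. For designated high-depth samples, reference
genotypes are called on the full read pool, then the pool is subsampled
*without replacement* over a fraction grid (0.1–0.9% in steps of 0.1%,
1–100% in steps of 1%; 109 fractions), emulating many sequencing passes at
increasing depth. Resampling operates on the whole sample's read pool, so
per-locus retained counts are multivariate hypergeometric — the exact model
of re-capturing a fraction of the sample's total reads.

Each (locus, sample, fraction) observation contributes its realized depth
and its agreement with the full-depth call to the depth bin of its
full-depth genotype class. *Concordance* per bin is the agreement fraction.
No depth threshold is applied inside the diagnostic — low-depth instability
is the quantity being measured, and the threshold is the output, not an
input.

Numerical policies (the continuous published curves do not state them, so
they are implementation choices, fixed here):

* depth bins are integer up to 50 reads, then geometric with ratio 1.3;
* the class threshold at confidence $c$ is the smallest bin lower edge at
  which concordance reaches $c$ **and stays at or above $c$ for every
  deeper observed bin** — a transient crossing of a noisy curve does not
  define a threshold;
* bins with fewer than 30 observations are skipped, not failed;
* when no depth qualifies, the threshold is reported as not achieved,
  together with the deepest bin observed.

Two analytic anchors validate the machinery. Error-free nulliplex markers
have a one-allele read pool, so any subsample reproduces the call and the
95% threshold is exactly 1 read. For simplex markers at $e = 0.005$ the
diagnostic agrees, within one depth bin, with the exact binomial
computation of the smallest $n$ such that the ML call of
$\mathrm{Binomial}(n, f(1))$ reads is simplex with probability $\ge 0.95$.
Per-class accuracy is not monotone in depth cell-by-cell (parity effects of
the ML decision boundaries), which is why thresholds are read from binned
curves with the stays-above rule.

# The synthetic-data generator

The generator defines the study conditions under which the package's
claims are tested.

* **Population structure** follows the Balding–Nichols model: ancestral
  frequencies $q$ uniform on the minor-allele window (default
  [0.05, 0.5], mirrored to $1-q$ with probability one half), and
  per-population frequencies Beta-distributed with parameters
  $q(1-F)/F$ and $(1-q)(1-F)/F$, so their variance is $q(1-q)F$. A single
  $F$ applies to all populations; the published study reports only realized
  pairwise FST values (0.017–0.110 between geographic regions), not a
  generative model, so this one-parameter model is the package's choice.
* **Genotypes** are polysomic Hardy–Weinberg draws:
  $d \sim \mathrm{Binomial}(p, q_\text{pop})$, with optional Dirichlet
  admixture. The allopolyploid-vs-autopolyploid ancestry debate is not
  modeled; hexasomic inheritance is assumed.
* **Subgenome labels** are drawn per locus (default proportions 85.7 :
  3.1 : 7.2 for both / A-only / B-only, the study-like read proportions
  renormalized to sum to one; the residual ~4% of real reads map to
  neither reference and carry no genotype). A locus therefore has exactly
  one ploidy context, matching per-genotype 6x/4x/2x classification.
* **Read depth** is negative binomial with mean `mean_depth` and
  dispersion 5 (Poisson in the large-dispersion limit). The published
  depth distribution is described only as "relatively uniform" across
  accessions and loci; the negative binomial is an implementation choice
  that produces the broad spread typical of GBS libraries.
* **Reads** (FASTQ) are an 8-bp buffer + a 6–9 bp sample barcode + a
  random insert, with constant Phred 38 qualities and an optional
  low-quality tail to exercise trimming; one substitution/insertion/
  deletion is injected into the barcode region at a configurable per-read
  rate. Simulated reads carry no locus identity — alignment is outside the
  package's scope — so the FASTQ/demultiplexing layer is validated on read
  accounting, not on genotypes.

What passing tests on these data do **not** show about real data: no
restriction-site or fragment-length biases, no PCR duplicates, no
paralogous or repetitive loci (the main published source of unstable
genotype calls), no per-cycle error profiles, and no indels/CNVs (only
biallelic SNP-like loci are simulated).

# Demultiplexing and barcode design

Barcodes are compared by Levenshtein distance (unit-cost substitutions,
insertions, deletions). Two policies matter in practice:

* **Decoding.** After buffer removal, each barcode of length $L$ is
  compared against read prefixes of lengths $L \pm$ `max_distance`, and the
  minimum distance is used — an indel shifts the barcode/insert boundary,
  and the fixed-length comparison would overcount such errors. A read is
  assigned to the unique barcode of minimal distance $\le$ `max_distance`
  (default 1; the maximum correctable error count is a design property of
  the barcode set, exposed as a flag because the published pipeline does
  not state its rescue distance). Minimal-distance ties between different
  samples leave the read unassigned; ties between lengths of the same
  sample prefer the longer barcode.
* **Design.** The pairwise separation enforced during barcode design is
  the *sequence-Levenshtein* distance: the minimum Levenshtein distance
  over all truncations of either barcode (equivalently, the row/column
  minima of the DP table). With plain Levenshtein separation, a short
  barcode whose read continues into random insert bases can collide with a
  longer barcode at the boundary; the truncation-closed metric removes
  exactly this failure mode. A floor of $2k + 1$ permits correction of $k$
  errors; with the default floor 3 and at most one barcode error per read,
  simulated demultiplexing is 100% accurate.

Quality trimming removes the 8-bp buffer and then trailing bases whose
quality is below Q36. The published criterion is a boxplot-over-cycles
reading (lower whisker at Q36); the per-read trailing rule used here
applies the same constant deterministically to any input read.

# Diversity and structure statistics

All statistics consume diploidized codes `{0, 1, 2, NA}`.

* **p-distance**: $d(i,j) = \sum_l |c_{il} - c_{jl}| / (2 L_{ij})$ over
  jointly called loci — the proportion of differing alleles, with
  heterozygote-homozygote pairs contributing one half. The exact character
  coding used by the published distance software is unstated; this
  definition realizes "proportion of variant alleles" on diploidized data.
* **Neighbor joining** (Saitou–Nei, Studier–Keppler criterion) on the
  p-distance matrix; exact on additive matrices. Interior-branch support is
  the bootstrap bipartition proportion over locus resampling (1000
  replicates by default) — an operational stand-in for the original
  interior-branch t-test with the same 50% collapse rule; branches below
  50% support collapse into polytomies.
* **FST**: Weir–Cockerham (1984) variance components accumulated as a
  ratio of sums over loci. The published study used a commercial package
  without naming its estimator; Weir–Cockerham is the community standard,
  and a Hudson-type estimator is available for sensitivity checks.
  Negative multi-locus estimates are reported as computed.
* **LD r^2** by expectation-maximization over the unphased 3x3 two-locus
  genotype table. Only the phase of double heterozygotes is hidden, so
  allele frequencies are fully observed and the EM effectively profiles
  the single parameter $D$; the implementation runs from the
  linkage-equilibrium start to convergence below 1e-10 (at most 1000
  iterations) and is vectorized across pairs. On data without double
  heterozygotes it equals the phased-count r^2 exactly.
* **LD pruning**: sliding window of 50 retained markers advanced by 5;
  within a window, a pair with r^2 > 0.5 removes the later (by position)
  marker, which never re-enters. The published package does not document
  its victim choice; the positional rule is deterministic.
* **LD decay**: r^2 of intra-chromosomal pairs aggregated in log-spaced
  distance bins; the crossing distance for a threshold is where the binned
  mean first falls below it and stays below, linearly interpolated between
  bin centers.
* **PCA** on additive 0/1/2 codes, missing imputed to the locus mean,
  loci mean-centered, no variance standardization by default; the sign of
  each component is fixed by making its largest-magnitude loading positive.
* **Evanno delta-K**:
  $\Delta K = |\bar L(K+1) - 2 \bar L(K) + \bar L(K-1)| / \mathrm{sd}(L(K))$
  from replicate admixture log-likelihoods; undefined at the endpoints and
  where the run standard deviation is zero. The admixture MCMC itself is
  out of scope — its outputs (log-likelihood tables, Q-matrices) are
  consumed, not produced.
* **Cluster assignment**: a sample joins the cluster whose ancestry
  proportion reaches the q threshold (default 0.65); otherwise it is
  admixed. Thresholds at or below 0.5 draw a warning because several
  clusters could qualify (the largest wins).

# Pipeline, seeding and problem sizes

`run_pipeline()` executes sim → demux → call → stability → filter → popgen
from a single configuration (in code or YAML), writing per-stage outputs
and a manifest with parameter snapshots, md5 checksums and conservation
counts (reads assigned + unassigned = simulated; locus counts never
increase across filters). All randomness flows from one master seed;
each stage, sample and resampling fraction derives its own seed by hashing
its label with the master seed (`derive_seed()`), so any stage can be
re-run in isolation and reproduce the full-pipeline result. Simulated
FASTQ reads carry no locus identity (alignment is abstracted), so the
demultiplexing stage validates read accounting while genotype read counts
come directly from the count simulator.

The test suite runs the chain at desk scale: the stability diagnostic on
50 samples x 50-150 loci at mean depth 400-500; estimator-recovery
experiments at 2 x 200 samples x 5000 loci; the end-to-end pipeline at 96
samples x 2000 loci. These sizes were chosen so each Monte-Carlo check has
comfortable margin while the whole suite stays interactive.

# Known limitations

* Weir–Cockerham theta on *diploidized hexaploid* codes is attenuated:
  the codes are an indicator transform of dosage, and the induced
  "allele frequency" $g(q) = \tfrac12(1 - (1-q)^p + q^p)$ compresses
  between-population variance by roughly half for typical frequencies
  (delta-method computation). Differentiation estimates on hexaploid data
  are therefore comparable between groups but not calibrated to the
  generative $F$; the estimator-recovery guarantee (±0.02) holds for true
  diploid genotypes, where diploidization is the identity.
* The caller assumes a symmetric, locus-independent error rate and
  unbiased allele sampling; allele-specific bias, paralogy and mapping
  error are not modeled.
* The interior-branch support is a bootstrap proportion, not the original
  branch-length t-test.
* No paired-end reads, adapter trimming, indel/CNV calling, or admixture
  MCMC.
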