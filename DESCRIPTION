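Package: polygbs
Title: Allele-Dosage Genotyping and Population Genetics for Polyploid GBS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genotyping-by-sequencing (GBS) of polyploids with two
    ancestral subgenomes, modelled on hexaploid sweetpotato. Provides
    edit-distance tolerant barcode design and demultiplexing, quality/buffer
    trimming, maximum-likelihood allele-dosage calling from ref/alt read
    counts under a per-locus ploidy context (2x/4x/6x), an empirical
    read-resampling stability diagnostic that derives per-genotype-class
    read-depth thresholds, variant filtering, and downstream diversity and
    structure statistics (minor-allele-frequency summaries, p-distance,
    neighbor-joining with bootstrap interior-branch support, Weir-Cockerham
    FST, EM-based linkage-disequilibrium r2 with windowed pruning and decay
    curves, PCA, Evanno delta-K and q-threshold cluster assignment). A
    synthetic-data generator produces hexaploid dosage genotypes under
    polysomic Hardy-Weinberg proportions with tunable population structure,
    overdispersed read depths and barcoded FASTQ reads, so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    S4Vectors,
    vcfR,
    optparse
Config/testthat/edition: 3
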