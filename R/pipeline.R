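#' Build a pipeline configuration
#'
#' Assembles the stage toggles and parameters of the end-to-end run:
#' simulation -> (FASTQ + demultiplexing) -> dosage calling -> stability
#' diagnostic -> filtering -> population-genetics statistics. Any element
#' can be overridden; unknown names are rejected.
#'
#' @param seed master integer seed (mandatory); every stage derives its own
#'   seed from it via [derive_seed()].
#' @param sim list of [sim_config()] arguments (without `seed`).
#' @param demux list: `enabled`, `n_reads_per_sample`, `n_barcode_samples`,
#'   `max_distance`, `min_barcode_distance`, `barcode_error_rate`,
#'   `min_quality`.
#' @param call list: `error_rate`, `uniform_depth_threshold`,
#'   `class_depth_thresholds`.
#' @param stability list: `enabled`, `n_high_depth_samples`, `confidence`
#'   (vector), `min_obs`.
#' @param filter list: `maf_min`, `max_missing`.
#' @param popgen list: `enabled`, `n_boot`, `collapse_below`, `ld_window`,
#'   `ld_step`, `ld_r2_max`, `n_components`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed,
                            sim = list(),
                            demux = list(),
                            call = list(),
                            stability = list(),
                            filter = list(),
                            popgen = list()) {
  if (missing(seed)) stop_param("a master seed is mandatory")
  defaults <- list(
    sim = list(n_pops = 2, fst = 0.05, n_samples_per_pop = 4, n_loci = 200,
               ploidy = 6, mean_depth = 80, depth_dispersion = 5,
               error_rate = 0.001),
    demux = list(enabled = TRUE, n_reads_per_sample = 200,
                 max_distance = 1, min_barcode_distance = 3,
                 barcode_error_rate = 0.02, min_quality = 36),
    call = list(error_rate = 0.001, uniform_depth_threshold = 45,
                class_depth_thresholds = NULL),
    stability = list(enabled = TRUE, n_high_depth_samples = 4,
                     confidence = c(0.95, 0.85), min_obs = 30,
                     mean_depth = 400),
    filter = list(maf_min = 0.05, max_missing = 0.20),
    popgen = list(enabled = TRUE, n_boot = 100, collapse_below = 50,
                  ld_window = 50, ld_step = 5, ld_r2_max = 0.5,
                  n_components = 5))
  merge_stage <- function(name, user) {
    d <- defaults[[name]]
    unknown <- setdiff(names(user), names(d))
    if (name == "sim") unknown <- setdiff(names(user), names(formals(sim_config)))
    if (length(unknown))
      stop_param("unknown ", name, " option(s): ", paste(unknown, collapse = ", "))
    utils::modifyList(d, user)
  }
  structure(list(seed = as.integer(seed),
                 sim = merge_stage("sim", sim),
                 demux = merge_stage("demux", demux),
                 call = merge_stage("call", call),
                 stability = merge_stage("stability", stability),
                 filter = merge_stage("filter", filter),
                 popgen = merge_stage("popgen", popgen)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds the same nested structure as [pipeline_config()]
#' (top-level `seed` plus per-stage blocks).
#'
#' @param path YAML path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop_param("config must set a seed")
  do.call(pipeline_config, y)
}

manifest_entry <- function(files) {
  files <- files[file.exists(files)]
  lapply(stats::setNames(as.list(files), basename(files)),
         function(f) unname(tools::md5sum(f)))
}

#' Run the end-to-end synthetic GBS pipeline
#'
#' Executes the enabled stages in order
#' sim -> demux -> call -> stability -> filter -> popgen, writing stage
#' outputs and a run manifest (parameter snapshot, per-file checksums,
#' conservation counts) under `out_dir`. Deterministic under a fixed master
#' seed; a stage failure aborts with the failing stage named, retaining the
#' outputs already written.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param out_dir output directory (created if needed).
#' @return the manifest list, invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, paste0(...))
  manifest <- list(seed = config$seed, parameters = unclass(config),
                   stages = list())
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- sim ---
  dataset <- run_stage("sim", function() {
    cfg <- do.call(sim_config, c(config$sim,
                                 list(seed = derive_seed(config$seed, "sim"))))
    ds <- simulate_gbs_dataset(cfg)
    write_counts_tsv(ds$counts, pth("counts.tsv"))
    write_genotypes_tsv(dosage_matrix(ds$counts$loci, ds$truth$true_dosages),
                        pth("true_dosages.tsv"))
    utils::write.table(
      data.frame(locus = locus_ids(ds$counts$loci),
                 ancestral = ds$truth$ancestral_freqs, ds$truth$pop_freqs),
      pth("frequencies.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    ds
  })
  n_samples <- ncol(dataset$counts$ref)
  manifest$stages$sim <- list(
    files = manifest_entry(pth(c("counts.tsv", "true_dosages.tsv",
                                 "frequencies.tsv"))),
    n_loci = nrow(dataset$counts$loci), n_samples = n_samples)

  # --- demux (barcode layer demonstration on simulated FASTQ) ---
  if (isTRUE(config$demux$enabled)) {
    manifest$stages$demux <- run_stage("demux", function() {
      dmx <- config$demux
      bc <- design_barcodes(n_samples, min_distance = dmx$min_barcode_distance,
                            seed = derive_seed(config$seed, "barcodes"))
      bc$sample_id <- sample_names(dataset$counts)
      plan <- stats::setNames(rep(dmx$n_reads_per_sample, n_samples),
                              bc$sample_id)
      simulate_fastq(plan, bc, pth("reads.fastq"), pth("manifest_reads.tsv"),
                     barcode_error_rate = dmx$barcode_error_rate,
                     seed = derive_seed(config$seed, "fastq"))
      reads <- read_fastq(pth("reads.fastq"))
      trimmed <- trim_reads(reads, buffer_length = 8,
                            min_quality = dmx$min_quality)
      res <- demultiplex(trimmed, bc, max_distance = dmx$max_distance,
                         buffer_length = 0)
      utils::write.table(res$report, pth("demux_report.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      n_assigned <- sum(res$report$n_reads[res$report$sample_id != "unassigned"])
      n_un <- res$report$n_reads[res$report$sample_id == "unassigned"]
      stopifnot(n_assigned + n_un + attr(trimmed, "n_discarded") ==
                  nrow(reads))
      list(files = manifest_entry(pth(c("reads.fastq", "manifest_reads.tsv",
                                        "demux_report.tsv"))),
           n_reads_simulated = nrow(reads),
           n_reads_discarded_trim = attr(trimmed, "n_discarded"),
           n_reads_assigned = n_assigned, n_reads_unassigned = n_un)
    })
  }

  # --- call ---
  calls <- run_stage("call", function() {
    cc <- caller_config(error_rate = config$call$error_rate,
                        uniform_depth_threshold = config$call$uniform_depth_threshold,
                        class_depth_thresholds = config$call$class_depth_thresholds)
    dos <- call_dosages(dataset$counts, cc)
    write_genotypes_tsv(dos, pth("dosages.tsv"))
    write_vcf(dos, pth("calls.vcf"), counts = dataset$counts)
    dip <- diploidize(dos)
    write_genotypes_tsv(dip, pth("diploidized.tsv"))
    list(dos = dos, dip = dip)
  })
  manifest$stages$call <- list(
    files = manifest_entry(pth(c("dosages.tsv", "calls.vcf",
                                 "diploidized.tsv"))),
    n_loci = nrow(calls$dos$loci),
    missing_fraction = mean(is.na(calls$dos$dosages)))

  # --- stability ---
  if (isTRUE(config$stability$enabled)) {
    manifest$stages$stability <- run_stage("stability", function() {
      stc <- config$stability
      # designated high-depth samples: fresh counts at diagnostic depth for
      # the first few samples
      k <- min(stc$n_high_depth_samples, n_samples)
      hd <- simulate_read_counts(
        dataset$truth$true_dosages[, seq_len(k), drop = FALSE],
        mean_depth = stc$mean_depth,
        depth_dispersion = config$sim$depth_dispersion,
        error_rate = config$sim$error_rate,
        subgenome_labels = dataset$truth$subgenome_labels,
        seed = derive_seed(config$seed, "stability_depth"))
      curve <- stability_curves(hd,
                                caller_config(error_rate = config$call$error_rate,
                                              uniform_depth_threshold = 0),
                                seed = derive_seed(config$seed, "stability"))
      utils::write.table(curve, pth("stability_curve.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      thr <- do.call(rbind, lapply(stc$confidence, function(cf)
        depth_thresholds(curve, cf, min_obs = stc$min_obs)))
      utils::write.table(thr, pth("depth_thresholds.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(files = manifest_entry(pth(c("stability_curve.tsv",
                                        "depth_thresholds.tsv"))),
           n_high_depth_samples = k)
    })
  }

  # --- filter ---
  filtered <- run_stage("filter", function() {
    f <- filter_variants(calls$dip, config$filter$maf_min,
                         config$filter$max_missing)
    write_genotypes_tsv(f, pth("filtered.tsv"))
    utils::write.table(attr(f, "report"), pth("filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })
  if (nrow(filtered$codes) > nrow(calls$dip$codes))
    stop("filter stage increased the locus count", call. = FALSE)
  manifest$stages$filter <- list(
    files = manifest_entry(pth(c("filtered.tsv", "filter_report.tsv"))),
    n_loci_in = nrow(calls$dip$codes), n_loci_out = nrow(filtered$codes))

  # --- popgen ---
  if (isTRUE(config$popgen$enabled)) {
    manifest$stages$popgen <- run_stage("popgen", function() {
      pg <- config$popgen
      groups <- if (is.matrix(dataset$truth$ancestry)) NULL else
        stats::setNames(dataset$truth$ancestry, sample_names(dataset$counts))
      maf <- maf_summary(filtered, groups)
      utils::write.table(maf$summary, pth("maf_summary.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      D <- p_distance(filtered)
      utils::write.table(round(D, 6), pth("distances.tsv"), sep = "\t",
                         quote = FALSE, col.names = NA)
      tree <- interior_branch_support(filtered, n_boot = pg$n_boot,
                                      collapse_below = pg$collapse_below,
                                      seed = derive_seed(config$seed, "boot"))
      ape::write.tree(tree, pth("nj_tree.nwk"))
      if (!is.null(groups) && length(unique(groups)) >= 2) {
        fst <- pairwise_fst(filtered, groups)
        utils::write.table(round(fst, 6), pth("fst.tsv"), sep = "\t",
                           quote = FALSE, col.names = NA)
      }
      pruned <- ld_prune(filtered, pg$ld_r2_max, pg$ld_window, pg$ld_step)
      writeLines(pruned$retained, pth("retained_loci.txt"))
      decay <- tryCatch(ld_decay(filtered), error = function(e) NULL)
      if (!is.null(decay))
        utils::write.table(decay$curve, pth("ld_decay.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      pca <- pca_genotypes(pruned$matrix,
                           min(pg$n_components, ncol(filtered$codes) - 1))
      utils::write.table(
        cbind(sample = rownames(pca$scores), as.data.frame(pca$scores)),
        pth("pca_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      list(files = manifest_entry(pth(c("maf_summary.tsv", "distances.tsv",
                                        "nj_tree.nwk", "fst.tsv",
                                        "retained_loci.txt", "ld_decay.tsv",
                                        "pca_scores.tsv"))),
           n_loci_pruned = length(pruned$retained))
    })
  }

  manifest_path <- pth("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}
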