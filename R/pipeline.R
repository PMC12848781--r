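#' Default pipeline configuration
#'
#' Collects every stage's numeric defaults in one flat, versioned list:
#' barcode correction at Levenshtein distance <= 2; NDR scan at
#' 100 bp windows / 20 bp steps, p < 1e-10, more than 5 GCH sites,
#' coverage >= 1; bin matrices at 250 kb with the >= 10 000-bins-per-cell
#' and >= 50%-cells-per-bin filters; 50 principal components; CNV windows
#' of 1 Mb at ploidy 2; the top 10% of age-correlated sites for the
#' clock. Simulation settings come from [sim_config()].
#'
#' @param seed integer master seed.
#' @param ... overrides for any field.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    config_version = "1",
    seed = as.integer(seed),
    barcode_max_dist = 2L,
    linker_max_mismatch = 1L,
    ndr_window = 100L, ndr_step = 20L, ndr_p_max = 1e-10,
    ndr_min_sites = 5L, ndr_min_coverage = 1L,
    bin_size = 250000L, min_bins_per_cell = 10000L,
    min_cell_fraction_per_bin = 0.5,
    n_pcs = 50L, knn_k = 15L, leiden_resolution = 1.0,
    cnv_window = 1000000L, cnv_ploidy = 2L,
    clock_top_fraction = 0.10, clock_min_sites = 100L,
    sim = list()
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (cfg$ndr_p_max >= 1 || cfg$ndr_p_max <= 0) {
    stop("ndr_p_max must lie in (0, 1)")
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the pipeline end to end on synthetic data
#'
#' Wires the stages in dependency order on simulator output: simulate ->
#' demultiplex -> align -> dedup -> call sites -> QC -> pseudo-bulk NDRs
#' -> bin matrix / clustering -> CNV profiles. Each stage writes its
#' outputs under `outdir` and the run ends with a JSON manifest listing
#' every output file with its content hash and the resolved
#' configuration, so identical seeds give identical manifests for the
#' deterministic stages.
#'
#' @param stage one of `"simulate"`, `"demux"`, `"methcall"`, `"ndr"`,
#'   `"matrix"`, `"cnv"`, `"all"`; stages other than `"simulate"` expect
#'   the upstream outputs in `outdir` and fail naming the producing
#'   stage when missing.
#' @param config a [pipeline_config()]; `config$sim` holds overrides
#'   for [sim_config()].
#' @param outdir output directory (created).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(stage = "all", config = pipeline_config(),
                         outdir = tempfile("scnome_run_")) {
  stage <- match.arg(stage, c("simulate", "demux", "methcall", "ndr",
                              "matrix", "cnv", "all"))
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c("simulate", "demux", "methcall", "ndr", "matrix", "cnv")
  } else stage
  log_line <- function(...) message("[scnome] ", sprintf(...))
  need <- function(path, producer) {
    if (!file.exists(path)) {
      stop(sprintf("missing %s; run the '%s' stage first", path, producer))
    }
    path
  }
  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))

  if ("simulate" %in% stages) {
    ref <- simulate_reference(scfg)
    sim <- simulate_reads(scfg, ref)
    write_fasta(ref$reference, file.path(outdir, "reference.fa"))
    write_fastq(sim$reads$read_id, sim$reads$seq1,
                file.path(outdir, "reads_R1.fastq"))
    write_fastq(sim$reads$read_id, sim$reads$seq2,
                file.path(outdir, "reads_R2.fastq"))
    utils::write.table(
      sim$truth$ndr_intervals, file.path(outdir, "truth_ndrs.bed"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(
      data.frame(read_id = names(sim$truth$cell_assignments),
                 cell = sim$truth$cell_assignments),
      file.path(outdir, "truth_cells.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    saveRDS(list(layout = sim$layout, truth = sim$truth, contexts = ref$contexts),
            file.path(outdir, "sim_state.rds"))
    log_line("simulate: %d reads, %d cells, %d planted NDRs",
             nrow(sim$reads), scfg$n_cells, nrow(sim$truth$ndr_intervals))
  }

  if ("demux" %in% stages) {
    state <- readRDS(need(file.path(outdir, "sim_state.rds"), "simulate"))
    reads <- read_fastq(need(file.path(outdir, "reads_R1.fastq"), "simulate"))
    names(reads)[2] <- "seq1"
    dmx <- demultiplex(reads, state$layout)
    saveRDS(dmx, file.path(outdir, "demux.rds"))
    jsonlite::write_json(dmx$report[c("n_total", "n_unknown_structure",
                                      "n_unknown_barcode", "n_assigned")],
                         file.path(outdir, "demux_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    log_line("demux: %d/%d assigned (%d unknown structure, %d unknown barcode)",
             dmx$report$n_assigned, dmx$report$n_total,
             dmx$report$n_unknown_structure, dmx$report$n_unknown_barcode)
  }

  if ("methcall" %in% stages) {
    state <- readRDS(need(file.path(outdir, "sim_state.rds"), "simulate"))
    dmx <- readRDS(need(file.path(outdir, "demux.rds"), "demux"))
    reference <- read_fasta(need(file.path(outdir, "reference.fa"), "simulate"))
    aln <- align_exact_bisulfite(dmx$assigned$genomic, reference)
    rec <- cbind(dmx$assigned[aln$mapped, c("read_id", "cell")],
                 aln[aln$mapped, c("chrom", "start", "strand", "seq_plus")])
    dd <- dedup_records(rec)
    calls <- call_sites(dd$records, state$contexts)
    write_calls(calls, file.path(outdir, "calls.tsv"))
    qc <- cell_qc(calls)
    utils::write.table(qc, file.path(outdir, "cell_qc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    saveRDS(dd$records, file.path(outdir, "records.rds"))
    log_line("methcall: %d mapped records (%d duplicates removed), %d call rows",
             nrow(dd$records), dd$n_removed, nrow(calls))
  }

  if ("ndr" %in% stages) {
    calls <- read_calls(need(file.path(outdir, "calls.tsv"), "methcall"))
    reference <- read_fasta(need(file.path(outdir, "reference.fa"), "simulate"))
    pooled <- pseudo_bulk(calls, context = "GCH")
    res <- call_ndrs(pooled, nchar(reference),
                     window = config$ndr_window, step = config$ndr_step,
                     p_max = config$ndr_p_max, min_sites = config$ndr_min_sites,
                     min_coverage = config$ndr_min_coverage)
    write_ndr_bed(res$ndrs, file.path(outdir, "ndrs.bed"))
    log_line("ndr: %d windows scanned, %d significant, %d NDRs",
             nrow(res$windows), nrow(res$significant), nrow(res$ndrs))
  }

  if ("matrix" %in% stages) {
    calls <- read_calls(need(file.path(outdir, "calls.tsv"), "methcall"))
    reference <- read_fasta(need(file.path(outdir, "reference.fa"), "simulate"))
    m <- build_bin_matrix(calls, nchar(reference),
                          bin_size = config$bin_size, channel = "WCG")
    # synthetic genomes have few bins; coverage filters scale with them
    minb <- min(config$min_bins_per_cell, max(1L, ncol(m$values) %/% 2L))
    m <- filter_matrix(m, minb, config$min_cell_fraction_per_bin)
    dense <- impute_mean(m)
    emb <- embed_and_cluster(dense, n_pcs = config$n_pcs, k = config$knn_k,
                             resolution = config$leiden_resolution,
                             seed = config$seed)
    utils::write.table(
      data.frame(cell = names(emb$cluster_labels),
                 cluster = as.integer(emb$cluster_labels),
                 umap1 = emb$umap_xy[, 1], umap2 = emb$umap_xy[, 2]),
      file.path(outdir, "clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("matrix: %d cells x %d bins, %d clusters",
             nrow(dense), ncol(dense), length(unique(emb$cluster_labels)))
  }

  if ("cnv" %in% stages) {
    records <- readRDS(need(file.path(outdir, "records.rds"), "methcall"))
    reference <- read_fasta(need(file.path(outdir, "reference.fa"), "simulate"))
    # megabase windows exceed synthetic chromosomes; scale down to ~10/chrom
    win <- min(config$cnv_window, max(1000L, nchar(reference)[[1]] %/% 10L))
    wc <- window_counts(records, nchar(reference), window = win)
    prof <- copy_ratio(wc, ploidy = config$cnv_ploidy)
    utils::write.table(
      cbind(prof$windows, t(prof$ratio)), file.path(outdir, "cnv_ratio.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("cnv: %d entities x %d windows, cv %.3f-%.3f",
             nrow(prof$ratio), ncol(prof$ratio), min(prof$cv), max(prof$cv))
  }

  manifest <- write_manifest(outdir, config, stages)
  invisible(manifest)
}

write_manifest <- function(outdir, config, stages) {
  files <- setdiff(list.files(outdir), "manifest.json")
  hashes <- vapply(file.path(outdir, files), function(f) {
    unname(tools::md5sum(f))
  }, character(1))
  manifest <- list(
    stages = stages,
    config = unclass(config),
    files = stats::setNames(as.list(unname(hashes)), files)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
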