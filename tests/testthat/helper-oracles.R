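# Independent oracles used across the suite. Each is a direct, naive
# implementation kept deliberately separate from the package's code
# paths.

# dynamic-programming Levenshtein distance
dp_levenshtein <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  d <- matrix(0L, length(av) + 1L, length(bv) + 1L)
  d[, 1] <- 0:length(av)
  d[1, ] <- 0:length(bv)
  for (i in seq_along(av)) {
    for (j in seq_along(bv)) {
      d[i + 1, j + 1] <- min(
        d[i, j + 1] + 1L,
        d[i + 1, j] + 1L,
        d[i, j] + (av[i] != bv[j])
      )
    }
  }
  d[length(av) + 1L, length(bv) + 1L]
}

# closed-form Pearson statistic for the 2x2 table [[a, b], [c, d]]
oracle_chi2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# direct trinucleotide scan of a genome string, both strands
oracle_context_scan <- function(seq, chrom = "chr1") {
  comp <- function(x) chartr("ACGT", "TGCA", x)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  rows <- list()
  label <- function(up, down) {
    if (up %in% c("A", "T") && down == "G") "WCG"
    else if (up == "G" && down %in% c("A", "C", "T")) "GCH"
    else if (up %in% c("A", "T") && down %in% c("A", "C", "T")) "WCH"
    else "EXCLUDED"
  }
  for (i in seq_len(n)) {
    if (bases[i] == "C") {
      up <- if (i > 1) bases[i - 1] else ""
      down <- if (i < n) bases[i + 1] else ""
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = i, strand = "+",
        context = if (up == "" || down == "") "EXCLUDED" else label(up, down),
        stringsAsFactors = FALSE)
    }
    if (bases[i] == "G") {
      up <- if (i < n) comp(bases[i + 1]) else ""
      down <- if (i > 1) comp(bases[i - 1]) else ""
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = i, strand = "-",
        context = if (up == "" || down == "") "EXCLUDED" else label(up, down),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# hypergeometric upper tail by explicit summation over overlap counts
oracle_hyper_upper <- function(overlap, size_a, size_b, universe) {
  ks <- overlap:min(size_a, size_b)
  sum(choose(size_b, ks) * choose(universe - size_b, size_a - ks)) /
    choose(universe, size_a)
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sc <- function(x) sum(choose(x, 2))
  expected <- sc(rowSums(tab)) * sc(colSums(tab)) / choose(n, 2)
  (sc(tab) - expected) / ((sc(rowSums(tab)) + sc(colSums(tab))) / 2 - expected)
}

# map demultiplexed cell labels ("A_B_index") back to truth cell names
truth_cell_of <- function(sim) {
  bc <- sim$truth$cell_barcodes
  stats::setNames(bc$cell, paste(bc$barcode_A, bc$barcode_B, bc$pcr_index,
                                 sep = "_"))
}

# small shared simulation used by several round-trip tests
small_sim <- function(seed = 3, n_cells = 6, reads_per_cell = 30,
                      conversion_failure = 0.005,
                      barcode_error_rate = 0, chrom_length = 40000L) {
  cfg <- sim_config(seed = seed, n_chromosomes = 1,
                    chrom_length = chrom_length, n_cells = n_cells,
                    reads_per_cell = reads_per_cell,
                    conversion_failure = conversion_failure,
                    barcode_error_rate = barcode_error_rate)
  ref <- simulate_reference(cfg)
  sim <- simulate_reads(cfg, ref)
  list(cfg = cfg, ref = ref, sim = sim)
}
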