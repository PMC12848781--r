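#' Configuration for the synthetic single-cell NOMe-seq generator
#'
#' Bundles every knob of the simulator: genome shape, cell numbers,
#' split-pool barcode inventory, bisulfite chemistry, methylation
#' landscape, planted accessible regions (NDRs), planted copy-number
#' clones, and sequencing-error rates. Defaults describe the desk-scale
#' regime the pipeline is validated on: a small random genome, a few
#' hundred cells barcoded with the 48 x 96 two-round ligation inventory,
#' a 0.5% bisulfite conversion-failure rate, and an accessibility
#' contrast of 0.8 (inside NDRs) versus 0.2 (background) GpC methylation.
#'
#' @param seed integer; all randomness flows from this single seed.
#' @param n_chromosomes,chrom_length genome shape in bp.
#' @param n_cells number of cells to simulate.
#' @param cells_per_tube cells pooled per tube in the final split
#'   (controls the expected barcode-collision rate).
#' @param n_barcodes_A,n_barcodes_B whitelist sizes for the two ligation
#'   rounds (defaults 48 and 96).
#' @param barcode_length length of each ligation barcode in bp.
#' @param conversion_failure probability an unmethylated cytosine
#'   survives bisulfite conversion (read as C).
#' @param background_gch_meth,ndr_gch_meth GpC methylation probability
#'   outside/inside planted NDRs; `ndr_gch_meth` must exceed
#'   `background_gch_meth`.
#' @param planted_ndrs data.frame (`chrom`, `start`, `end`; 0-based
#'   half-open) of planted accessible regions, or `NULL` to plant
#'   `n_ndrs` regions of width `ndr_width` at random.
#' @param n_ndrs,ndr_width used only when `planted_ndrs` is `NULL`.
#' @param cpg_island_meth,gene_body_meth WCG methylation probability in
#'   planted hypomethylated islands and elsewhere.
#' @param planted_islands data.frame of CpG-island-like hypomethylated
#'   intervals (`chrom`, `start`, `end`), or `NULL` for none.
#' @param planted_cnv data.frame (`clone`, `chrom`, `start`, `end`,
#'   `copy_number`) of copy-number segments per clone, or `NULL`.
#' @param clone_of integer vector assigning each cell to a clone
#'   (recycled); clone 1 is diploid unless `planted_cnv` says otherwise.
#' @param reads_per_cell,read_length sequencing depth and read-1 length.
#' @param barcode_error_rate per-base substitution probability inside
#'   barcode segments.
#' @param cell_ages numeric vector of per-cell ages in years (recycled),
#'   used by the ageing simulations.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 100000L,
                       n_cells = 96L,
                       cells_per_tube = 200L,
                       n_barcodes_A = 48L,
                       n_barcodes_B = 96L,
                       barcode_length = 8L,
                       conversion_failure = 0.005,
                       background_gch_meth = 0.2,
                       ndr_gch_meth = 0.8,
                       planted_ndrs = NULL,
                       n_ndrs = 4L,
                       ndr_width = 600L,
                       cpg_island_meth = 0.1,
                       gene_body_meth = 0.8,
                       planted_islands = NULL,
                       planted_cnv = NULL,
                       clone_of = 1L,
                       reads_per_cell = 50L,
                       read_length = 100L,
                       barcode_error_rate = 0) {
  probs <- c(conversion_failure, background_gch_meth, ndr_gch_meth,
             cpg_island_meth, gene_body_meth, barcode_error_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (ndr_gch_meth <= background_gch_meth) {
    stop("ndr_gch_meth must exceed background_gch_meth")
  }
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_cells = as.integer(n_cells),
    cells_per_tube = as.integer(cells_per_tube),
    n_barcodes_A = as.integer(n_barcodes_A),
    n_barcodes_B = as.integer(n_barcodes_B),
    barcode_length = as.integer(barcode_length),
    conversion_failure = conversion_failure,
    background_gch_meth = background_gch_meth,
    ndr_gch_meth = ndr_gch_meth,
    planted_ndrs = planted_ndrs,
    n_ndrs = as.integer(n_ndrs),
    ndr_width = as.integer(ndr_width),
    cpg_island_meth = cpg_island_meth,
    gene_body_meth = gene_body_meth,
    planted_islands = planted_islands,
    planted_cnv = planted_cnv,
    clone_of = as.integer(clone_of),
    reads_per_cell = as.integer(reads_per_cell),
    read_length = as.integer(read_length),
    barcode_error_rate = barcode_error_rate
  )
  if (!is.null(planted_ndrs)) {
    check_intervals(planted_ndrs, cfg)
  }
  class(cfg) <- "sim_config"
  cfg
}

check_intervals <- function(iv, cfg) {
  stopifnot(all(c("chrom", "start", "end") %in% names(iv)))
  if (any(iv$start < 0) || any(iv$end > cfg$chrom_length) ||
      any(iv$end <= iv$start)) {
    stop("planted intervals must be 0-based half-open within chromosome bounds")
  }
  invisible(iv)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a reference genome with cytosine-context annotation
#'
#' Generates `n_chromosomes` uniform-random chromosomes and annotates
#' every cytosine on both strands with its WCG/GCH/WCH/EXCLUDED context
#' using the same classifier the methylation caller applies
#' ([annotate_contexts()]), so simulator truth and caller agree by
#' construction.
#'
#' @param cfg a [sim_config()].
#' @return list with `reference` (named character vector of chromosome
#'   sequences, names `chr1..chrN`) and `contexts` (data.frame from
#'   [annotate_contexts()]).
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$chrom_length < cfg$read_length) {
    stop("chromosome length must be at least the read length")
  }
  withr_seed(cfg$seed, {
    reference <- vapply(seq_len(cfg$n_chromosomes),
                        function(i) random_dna(cfg$chrom_length), character(1))
  })
  names(reference) <- paste0("chr", seq_len(cfg$n_chromosomes))
  list(reference = reference, contexts = annotate_contexts(reference))
}

# run code under a local RNG state seeded deterministically
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic whitelist with pairwise Levenshtein distance >= 3, so the
# <=2-distance correction rule is well-posed: rejection-sample candidates
# against the accepted set.
#' Generate a barcode whitelist with guaranteed pairwise distance
#'
#' @param n number of barcodes.
#' @param length barcode length in bp.
#' @param min_dist minimum pairwise Levenshtein distance (default 3,
#'   making single- and double-error correction unambiguous).
#' @param seed integer seed.
#' @return character vector of `n` barcodes.
#' @export
generate_whitelist <- function(n, length = 8L, min_dist = 3L, seed = 1L) {
  withr_seed(seed, {
    accepted <- character(0)
    tries <- 0L
    while (base::length(accepted) < n) {
      cand <- random_dna(length)
      tries <- tries + 1L
      if (tries > 200000L) stop("could not build whitelist; increase barcode length")
      if (base::length(accepted) == 0L ||
          min(utils::adist(cand, accepted)) >= min_dist) {
        accepted <- c(accepted, cand)
      }
    }
    accepted
  })
}

build_methylome_probs <- function(cfg, contexts) {
  # per-site Bernoulli methylation probability by context and planted features
  p <- numeric(nrow(contexts))
  wcg <- contexts$context == "WCG"
  gch <- contexts$context == "GCH"
  p[wcg] <- cfg$gene_body_meth
  p[gch] <- cfg$background_gch_meth
  # WCH / EXCLUDED stay 0: truly unmethylated, so residual C reads measure
  # conversion failure
  mark <- function(iv, sel, prob) {
    for (k in seq_len(nrow(iv))) {
      hit <- sel & contexts$chrom == iv$chrom[k] &
        contexts$pos - 1L >= iv$start[k] & contexts$pos - 1L < iv$end[k]
      p[hit] <<- prob
    }
  }
  if (!is.null(cfg$planted_ndrs)) mark(cfg$planted_ndrs, gch, cfg$ndr_gch_meth)
  if (!is.null(cfg$planted_islands)) mark(cfg$planted_islands, wcg, cfg$cpg_island_meth)
  p
}

default_planted_ndrs <- function(cfg) {
  # evenly spaced NDRs on chr1, away from chromosome ends
  width <- min(cfg$ndr_width, cfg$chrom_length %/% (2L * cfg$n_ndrs))
  upper <- cfg$chrom_length - width - 1L
  starts <- round(seq(cfg$chrom_length * 0.05, min(cfg$chrom_length * 0.9, upper),
                      length.out = cfg$n_ndrs))
  data.frame(chrom = "chr1", start = starts, end = starts + width)
}

#' Simulate barcoded bisulfite reads with ground truth
#'
#' Emulates the split-pool library structure: read 1 is
#' `linker1 + barcodeB + linker2 + barcodeA + genomic`, with the PCR index
#' carried in the read header. Bisulfite chemistry is applied
#' strand-correctly: fragments are drawn from either genomic strand; on
#' the fragment's own strand unmethylated cytosines convert to T with
#' probability `1 - conversion_failure` while methylated cytosines stay
#' C. Barcode bases are corrupted at `barcode_error_rate`. Per-cell
#' methylation states are drawn once per covered site, so multiple reads
#' over a site agree with the truth sidecar.
#'
#' @param cfg a [sim_config()]; if `cfg$planted_ndrs` is `NULL`,
#'   `n_ndrs` regions are planted first.
#' @param ref output of [simulate_reference()].
#' @return list with
#'   * `layout`: the [read_layout()] used (linkers, whitelists);
#'   * `reads`: data.frame `read_id`, `seq1` (structured read 1), `seq2`
#'     (mate, genomic only), `pcr_index`;
#'   * `truth`: list with `cell_assignments` (read -> cell),
#'     `cell_barcodes`, `cell_clones`, `cell_ages`, `ndr_intervals`,
#'     `site_states` (data.frame cell/chrom/pos/strand/context/state),
#'     and per-read origin (`chrom`, `start` 0-based, `strand`).
#' @export
simulate_reads <- function(cfg, ref) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$planted_ndrs)) cfg$planted_ndrs <- default_planted_ndrs(cfg)
  check_intervals(cfg$planted_ndrs, cfg)
  reference <- ref$reference
  contexts <- ref$contexts
  site_p <- build_methylome_probs(cfg, contexts)
  # fast lookup: per (chrom, strand) an integer vector over positions
  site_key <- paste0(contexts$chrom, ":", contexts$pos, ":", contexts$strand)

  wlA <- generate_whitelist(cfg$n_barcodes_A, cfg$barcode_length, seed = cfg$seed + 101L)
  wlB <- generate_whitelist(cfg$n_barcodes_B, cfg$barcode_length, seed = cfg$seed + 202L)
  linker1 <- withr_seed(cfg$seed + 303L, random_dna(6L))
  linker2 <- withr_seed(cfg$seed + 404L, random_dna(6L))
  layout <- read_layout(linker1 = linker1, linker2 = linker2,
                        barcode_length = cfg$barcode_length,
                        whitelist_A = wlA, whitelist_B = wlB)
  genomic_len <- cfg$read_length - layout$genomic_offset
  stopifnot(genomic_len >= 20L)

  withr_seed(cfg$seed + 505L, {
    n_cells <- cfg$n_cells
    clones <- rep_len(cfg$clone_of, n_cells)
    ages <- rep_len(50, n_cells)
    # unique barcode combination per cell (no planted collisions: collision
    # statistics are studied analytically/Monte-Carlo in the demux module)
    combos <- expand.grid(A = wlA, B = wlB, stringsAsFactors = FALSE)
    pick <- sample.int(nrow(combos), n_cells)
    cell_bc <- combos[pick, , drop = FALSE]
    cell_ids <- sprintf("cell%03d", seq_len(n_cells))
    pcr_index <- rep("PCR01", n_cells)

    # per-clone read-position weights implement planted CNVs
    chrom_names <- names(reference)
    chrom_len <- cfg$chrom_length
    clone_weights <- lapply(sort(unique(clones)), function(cl) {
      segs <- cfg$planted_cnv
      if (!is.null(segs)) segs <- segs[segs$clone == cl, , drop = FALSE]
      list(segs = segs)
    })
    names(clone_weights) <- as.character(sort(unique(clones)))

    all_reads <- vector("list", n_cells)
    all_states <- vector("list", n_cells)
    max_start <- chrom_len - genomic_len
    for (ci in seq_len(n_cells)) {
      nr <- cfg$reads_per_cell
      chrom <- sample(chrom_names, nr, replace = TRUE)
      start0 <- sample.int(max_start + 1L, nr, replace = TRUE) - 1L
      # copy-number gain: resample extra reads into amplified segments
      segs <- clone_weights[[as.character(clones[ci])]]$segs
      if (!is.null(segs) && nrow(segs) > 0) {
        for (k in seq_len(nrow(segs))) {
          extra_frac <- (segs$copy_number[k] - 2) / 2 *
            (segs$end[k] - segs$start[k]) / (length(chrom_names) * chrom_len)
          n_extra <- stats::rbinom(1L, nr, max(0, extra_frac))
          if (n_extra > 0) {
            idx <- sample.int(nr, n_extra)
            chrom[idx] <- segs$chrom[k]
            start0[idx] <- segs$start[k] +
              sample.int(max(1L, segs$end[k] - segs$start[k] - genomic_len), n_extra,
                         replace = TRUE) - 1L
          }
        }
      }
      strand <- sample(c("+", "-"), nr, replace = TRUE)
      frag <- substring(reference[chrom], start0 + 1L, start0 + genomic_len)

      # collect covered cytosine sites for this cell, draw one state each
      site_rows <- collect_covered_sites(contexts, chrom, start0, genomic_len)
      states <- stats::rbinom(length(site_rows), 1L, site_p[site_rows])
      state_of <- states
      names(state_of) <- site_key[site_rows]

      seqs <- apply_bisulfite(frag, chrom, start0, strand, state_of,
                              cfg$conversion_failure)
      bcA <- corrupt(rep(cell_bc$A[ci], nr), cfg$barcode_error_rate)
      bcB <- corrupt(rep(cell_bc$B[ci], nr), cfg$barcode_error_rate)
      read1 <- paste0(linker1, bcB, linker2, bcA, seqs)
      mate_start <- start0  # mate covers the same fragment, opposite strand
      seq2 <- dna_revcomp(seqs)
      rid <- sprintf("%s_r%05d", cell_ids[ci], seq_len(nr))
      all_reads[[ci]] <- data.frame(
        read_id = rid, seq1 = read1, seq2 = seq2,
        pcr_index = pcr_index[ci],
        cell = cell_ids[ci], chrom = chrom, start = start0, strand = strand,
        stringsAsFactors = FALSE
      )
      all_states[[ci]] <- data.frame(
        cell = cell_ids[ci],
        chrom = contexts$chrom[site_rows],
        pos = contexts$pos[site_rows],
        strand = contexts$strand[site_rows],
        context = contexts$context[site_rows],
        state = states,
        stringsAsFactors = FALSE
      )
    }
    reads <- do.call(rbind, all_reads)
    truth <- list(
      cell_assignments = stats::setNames(reads$cell, reads$read_id),
      cell_barcodes = data.frame(cell = cell_ids, barcode_A = cell_bc$A,
                                 barcode_B = cell_bc$B, pcr_index = pcr_index,
                                 stringsAsFactors = FALSE),
      cell_clones = stats::setNames(clones, cell_ids),
      cell_ages = stats::setNames(ages, cell_ids),
      ndr_intervals = cfg$planted_ndrs,
      site_states = do.call(rbind, all_states),
      read_origin = reads[, c("read_id", "chrom", "start", "strand")]
    )
    list(layout = layout,
         reads = reads[, c("read_id", "seq1", "seq2", "pcr_index")],
         truth = truth)
  })
}

# indices into `contexts` of cytosines covered by >=1 fragment
collect_covered_sites <- function(contexts, chrom, start0, len) {
  hits <- integer(0)
  for (ch in unique(chrom)) {
    sel <- which(contexts$chrom == ch)
    if (!length(sel)) next
    iv <- IRanges::IRanges(start = start0[chrom == ch] + 1L, width = len)
    iv <- IRanges::reduce(iv)
    pos <- IRanges::IRanges(start = contexts$pos[sel], width = 1L)
    ov <- IRanges::overlapsAny(pos, iv)
    hits <- c(hits, sel[ov])
  }
  sort(unique(hits))
}

# apply bisulfite chemistry to plus-oriented fragments, then orient reads:
# '+' fragments are read as-is; '-' fragments are read as the reverse
# complement of the converted minus strand, i.e. G->A changes in plus
# orientation.
apply_bisulfite <- function(frag, chrom, start0, strand, state_of, conv_fail) {
  n <- length(frag)
  out <- character(n)
  for (i in seq_len(n)) {
    bases <- strsplit(frag[i], "", fixed = TRUE)[[1]]
    if (strand[i] == "+") {
      cpos <- which(bases == "C")
      key <- paste0(chrom[i], ":", start0[i] + cpos, ":+")
    } else {
      cpos <- which(bases == "G")  # minus-strand cytosines in plus orientation
      key <- paste0(chrom[i], ":", start0[i] + cpos, ":-")
    }
    if (length(cpos)) {
      st <- state_of[key]
      st[is.na(st)] <- 0L  # unannotated (shouldn't happen) -> unmethylated
      convert <- st == 0L & stats::runif(length(cpos)) > conv_fail
      bases[cpos[convert]] <- if (strand[i] == "+") "T" else "A"
    }
    seq_plus <- paste(bases, collapse = "")
    out[i] <- if (strand[i] == "+") seq_plus else dna_revcomp(seq_plus)
  }
  out
}

corrupt <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    bases <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(bases)) < rate
    if (any(hit)) {
      bases[hit] <- vapply(bases[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
    }
    paste(bases, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate pooled site-level GpC (or WCH) methylation counts
#'
#' Generates pseudo-bulk per-site counts directly at the methylation-call
#' level: per-site coverage is Poisson with the given mean and methylated
#' counts are binomial at the site's probability (inside planted NDRs,
#' `ndr_gch_meth`; outside, `background_gch_meth`). This is the input
#' regime of the NDR caller, without the cost of simulating and aligning
#' individual reads.
#'
#' @param cfg a [sim_config()] (uses the GCH probabilities and planted
#'   NDRs; plants defaults if `NULL`).
#' @param ref output of [simulate_reference()].
#' @param mean_coverage mean per-site pooled coverage (e.g. 50).
#' @param context context class to simulate (`"GCH"` or `"WCH"`).
#' @param meth_prob overrides the per-site probability entirely
#'   (e.g. a conversion-failure rate when simulating WCH sites).
#' @return data.frame `chrom`, `pos`, `strand`, `context`, `meth`,
#'   `total` with `total >= 1` rows only.
#' @export
simulate_pooled_gch <- function(cfg, ref, mean_coverage = 50,
                                context = "GCH", meth_prob = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$planted_ndrs)) cfg$planted_ndrs <- default_planted_ndrs(cfg)
  contexts <- ref$contexts
  sel <- contexts$context == context
  sites <- contexts[sel, , drop = FALSE]
  p <- if (is.null(meth_prob)) build_methylome_probs(cfg, contexts)[sel]
       else rep(meth_prob, nrow(sites))
  withr_seed(cfg$seed + 606L, {
    total <- stats::rpois(nrow(sites), mean_coverage)
    meth <- stats::rbinom(nrow(sites), total, p)
  })
  keep <- total >= 1L
  data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
             strand = sites$strand[keep], context = context,
             meth = meth[keep], total = total[keep],
             stringsAsFactors = FALSE)
}

#' Simulate per-cell methylation call tables for cell groups
#'
#' Gives each group its own bin-level WCG methylation profile (baseline
#' plus group-specific deviations in a random subset of bins), then
#' draws sparse single-cell call tables from it: each cell covers a
#' random subset of WCG sites at 1x and its binary calls are Bernoulli
#' at the bin's group probability. The regime mimics what distinguishes
#' cell types in bin-matrix clustering — coherent regional methylation
#' differences read through sparse per-cell coverage.
#'
#' @param ref output of [simulate_reference()].
#' @param group_of named integer/character vector cell -> group.
#' @param bin_size width of the profile bins in bp.
#' @param sites_per_cell WCG sites covered per cell.
#' @param baseline baseline methylation probability.
#' @param effect absolute deviation applied in differential bins.
#' @param frac_diff_bins fraction of bins that are differential per
#'   group.
#' @param seed integer seed.
#' @return methylation-call table (`cell`, `chrom`, `pos`, `strand`,
#'   `context`, `meth`, `total`).
#' @export
simulate_group_calls <- function(ref, group_of, bin_size = 10000L,
                                 sites_per_cell = 2000L,
                                 baseline = 0.5, effect = 0.3,
                                 frac_diff_bins = 0.5, seed = 1L) {
  contexts <- ref$contexts
  wcg <- contexts[contexts$context == "WCG", , drop = FALSE]
  bin_of <- paste0(wcg$chrom, ":", (wcg$pos - 1L) %/% bin_size)
  bins <- unique(bin_of)
  groups <- unique(as.character(group_of))
  withr_seed(seed, {
    prob_of <- lapply(groups, function(g) {
      p <- rep(baseline, length(bins))
      hit <- sample.int(length(bins), round(frac_diff_bins * length(bins)))
      p[hit] <- baseline + sample(c(-effect, effect), length(hit), replace = TRUE)
      stats::setNames(pmin(pmax(p, 0.02), 0.98), bins)
    })
    names(prob_of) <- groups
    out <- lapply(names(group_of), function(cell) {
      g <- as.character(group_of[[cell]])
      take <- sort(sample.int(nrow(wcg), min(sites_per_cell, nrow(wcg))))
      p <- prob_of[[g]][bin_of[take]]
      data.frame(
        cell = cell,
        chrom = wcg$chrom[take], pos = wcg$pos[take],
        strand = wcg$strand[take], context = "WCG",
        meth = stats::rbinom(length(take), 1L, p), total = 1L,
        stringsAsFactors = FALSE
      )
    })
  })
  do.call(rbind, out)
}

#' Simulate aligned read positions for copy-number analysis
#'
#' Draws per-cell read start positions uniformly along the genome,
#' with density scaled by each clone's local copy number (diploid = 2),
#' producing the deduplicated-record regime the read-depth CNV caller
#' consumes — without simulating sequences.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param planted_cnv data.frame `clone`, `chrom`, `start`, `end`,
#'   `copy_number` (0-based half-open), or `NULL` for all-diploid.
#' @param clone_of named integer vector cell -> clone.
#' @param reads_per_cell expected reads per diploid genome copy.
#' @param seed integer seed.
#' @return data.frame `cell`, `chrom`, `start` (0-based), `strand`.
#' @export
simulate_cnv_records <- function(chrom_lengths, planted_cnv, clone_of,
                                 reads_per_cell = 1000L, seed = 1L) {
  chroms <- names(chrom_lengths)
  withr_seed(seed, {
    out <- lapply(names(clone_of), function(cell) {
      cl <- clone_of[[cell]]
      # piecewise-constant copy number along the concatenated genome
      segs <- do.call(rbind, lapply(chroms, function(ch) {
        data.frame(chrom = ch, start = 0L, end = chrom_lengths[[ch]],
                   cn = 2, stringsAsFactors = FALSE)
      }))
      if (!is.null(planted_cnv)) {
        pc <- planted_cnv[planted_cnv$clone == cl, , drop = FALSE]
        pieces <- list()
        for (i in seq_len(nrow(segs))) {
          s <- segs[i, ]
          hits <- pc[pc$chrom == s$chrom, , drop = FALSE]
          if (!nrow(hits)) { pieces[[length(pieces) + 1L]] <- s; next }
          bounds <- sort(unique(c(s$start, s$end, hits$start, hits$end)))
          for (j in seq_len(length(bounds) - 1L)) {
            cn <- 2
            inside <- hits$start <= bounds[j] & hits$end >= bounds[j + 1L]
            if (any(inside)) cn <- hits$copy_number[which(inside)[1]]
            pieces[[length(pieces) + 1L]] <- data.frame(
              chrom = s$chrom, start = bounds[j], end = bounds[j + 1L],
              cn = cn, stringsAsFactors = FALSE)
          }
        }
        segs <- do.call(rbind, pieces)
      }
      w <- (segs$end - segs$start) * segs$cn / 2
      n <- stats::rpois(1L, reads_per_cell * sum(w) / sum(segs$end - segs$start))
      pick <- sample.int(nrow(segs), n, replace = TRUE, prob = w)
      data.frame(
        cell = cell,
        chrom = segs$chrom[pick],
        start = as.integer(segs$start[pick] +
          floor(stats::runif(n) * (segs$end[pick] - segs$start[pick]))),
        strand = sample(c("+", "-"), n, replace = TRUE),
        stringsAsFactors = FALSE
      )
    })
  })
  do.call(rbind, out)
}

#' Simulate single-cell binarized methylation states from an age model
#'
#' Draws, for each cell, a random subset of the model's predictive
#' sites as "covered" and a Bernoulli methylation state per covered
#' site with success probability `clamp(intercept + slope * age, clip,
#' 1 - clip)` — the generative counterpart of the profile-likelihood
#' age predictor, used for parameter-recovery checks.
#'
#' @param model an `age_model` from [train_age_model()].
#' @param ages numeric vector of true cell ages (one cell per entry).
#' @param n_sites_covered predictive sites covered per cell.
#' @param offset constant added to every site probability before
#'   clamping (a tumour-like hypermethylation shift when positive).
#' @param clip probability clamp (default 0.001).
#' @param seed integer seed.
#' @return list `states` (list of named 0/1 vectors, one per cell),
#'   `ages` (named by cell).
#' @export
simulate_clock_cells <- function(model, ages, n_sites_covered = 2000L,
                                 offset = 0, clip = 0.001, seed = 1L) {
  stopifnot(inherits(model, "age_model"))
  n_sites_covered <- min(n_sites_covered, length(model$selected))
  withr_seed(seed, {
    cells <- sprintf("cell%03d", seq_along(ages))
    states <- lapply(seq_along(ages), function(i) {
      sites <- sample(model$selected, n_sites_covered)
      p <- model$intercept[sites] + model$slope[sites] * ages[i] + offset
      p <- pmin(pmax(p, clip), 1 - clip)
      stats::setNames(stats::rbinom(length(sites), 1L, p), sites)
    })
    names(states) <- cells
    list(states = states, ages = stats::setNames(ages, cells))
  })
}

#' Simulate a bulk methylation reference for clock training
#'
#' Emulates a methylation-array reference cohort: a stated fraction of
#' sites have beta values linear in age (slopes drawn uniformly from
#' +/- [slope_min, slope_max] per year, intercepts uniform, values
#' clipped to \[0, 1\]), the remainder are age-independent; Gaussian
#' noise is added on top. True slopes are returned for
#' parameter-recovery checks.
#'
#' @param n_samples number of reference samples (must be >= 20).
#' @param n_sites number of CpG sites.
#' @param age_range numeric length-2, years; must span a positive range.
#' @param noise_sd Gaussian noise sd on beta values.
#' @param frac_age_linear fraction of sites with age-linear beta.
#' @param slope_range absolute per-year slope range for age-linear sites.
#' @param seed integer seed.
#' @return list with `beta` (samples x sites matrix, values in \[0,1\]),
#'   `ages`, `true_slopes` (0 for age-independent sites), `site_ids`.
#' @export
simulate_age_reference <- function(n_samples = 100L, n_sites = 2000L,
                                   age_range = c(30, 80), noise_sd = 0.05,
                                   frac_age_linear = 0.3,
                                   slope_range = c(0.002, 0.008),
                                   seed = 1L) {
  if (n_samples < 20L) stop("need at least 20 reference samples")
  if (diff(range(age_range)) <= 0) stop("age_range must span a positive range")
  withr_seed(seed, {
    ages <- stats::runif(n_samples, age_range[1], age_range[2])
    n_lin <- round(frac_age_linear * n_sites)
    slopes <- numeric(n_sites)
    slopes[seq_len(n_lin)] <- sample(c(-1, 1), n_lin, replace = TRUE) *
      stats::runif(n_lin, slope_range[1], slope_range[2])
    # intercepts chosen so the linear trend stays mostly inside [0,1]
    intercepts <- stats::runif(n_sites, 0.2, 0.8) -
      slopes * mean(age_range)
    beta <- outer(ages, slopes) +
      matrix(intercepts, n_samples, n_sites, byrow = TRUE)
    if (noise_sd > 0) beta <- beta + stats::rnorm(length(beta), 0, noise_sd)
    beta <- pmin(pmax(beta, 0), 1)
    site_ids <- sprintf("cg%06d", seq_len(n_sites))
    colnames(beta) <- site_ids
    rownames(beta) <- sprintf("sample%03d", seq_len(n_samples))
    list(beta = beta, ages = ages, true_slopes = slopes, site_ids = site_ids)
  })
}
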