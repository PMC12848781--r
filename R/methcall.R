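#' Toy exact bisulfite aligner for synthetic genomes
#'
#' Maps bisulfite-converted genomic subsequences to a small reference by
#' three-letter collapse and exact matching. All four strand
#' combinations are searched: the read and its reverse complement, each
#' collapsed C->T (against the C->T-collapsed plus strand) and G->A
#' (against the G->A-collapsed plus strand). A read is mapped only if
#' exactly one locus is hit across all combinations; multi-locus or
#' absent reads are unmapped. Collapsing makes alignment invariant to
#' methylation state, so a fully methylated read maps identically to its
#' unmethylated twin.
#'
#' Production data should go through a real bisulfite aligner; this
#' exact matcher exists so synthetic end-to-end runs need no external
#' binaries.
#'
#' @param seqs character vector of equal-length genomic subsequences
#'   (post-demultiplexing).
#' @param reference named character vector of chromosome sequences
#'   (<= 10 Mb total).
#' @return data.frame `mapped` (logical), `chrom`, `start` (0-based),
#'   `strand` (`"+"` if the read informs plus-strand cytosines, `"-"`
#'   for minus), `seq_plus` (read sequence in plus-strand orientation).
#' @export
align_exact_bisulfite <- function(seqs, reference) {
  reference <- as_reference(reference)
  stopifnot(sum(nchar(reference)) <= 10e6)
  widths <- unique(nchar(seqs))
  n <- length(seqs)
  out <- data.frame(mapped = logical(n), chrom = NA_character_,
                    start = NA_integer_, strand = NA_character_,
                    seq_plus = NA_character_, stringsAsFactors = FALSE)
  ref_ct <- Biostrings::DNAStringSet(chartr("C", "T", reference))
  ref_ga <- Biostrings::DNAStringSet(chartr("G", "A", reference))
  rc <- dna_revcomp(seqs)
  for (w in widths) {
    sel <- which(nchar(seqs) == w)
    # search spaces: (query, collapsed ref, strand of informed cytosines,
    # plus-oriented sequence)
    spaces <- list(
      list(q = chartr("C", "T", seqs[sel]), ref = ref_ct, strand = "+", plus = seqs[sel]),
      list(q = chartr("C", "T", rc[sel]),   ref = ref_ct, strand = "+", plus = rc[sel]),
      list(q = chartr("G", "A", seqs[sel]), ref = ref_ga, strand = "-", plus = seqs[sel]),
      list(q = chartr("G", "A", rc[sel]),   ref = ref_ga, strand = "-", plus = rc[sel])
    )
    hits <- vector("list", length(sel))
    for (sp in spaces) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(sp$q))
      for (ci in seq_along(sp$ref)) {
        m <- Biostrings::matchPDict(pd, sp$ref[[ci]])
        starts <- BiocGenerics::start(m)
        found <- which(lengths(starts) > 0L)
        for (i in found) {
          loci <- data.frame(chrom = names(reference)[ci],
                             start = starts[[i]] - 1L,
                             strand = sp$strand, seq_plus = sp$plus[i],
                             stringsAsFactors = FALSE)
          hits[[i]] <- rbind(hits[[i]], loci)
        }
      }
    }
    for (i in seq_along(sel)) {
      h <- hits[[i]]
      if (is.null(h)) next
      h <- unique(h[, c("chrom", "start", "strand", "seq_plus")])
      if (nrow(h) == 1L) {
        out$mapped[sel[i]] <- TRUE
        out$chrom[sel[i]] <- h$chrom
        out$start[sel[i]] <- h$start
        out$strand[sel[i]] <- h$strand
        out$seq_plus[sel[i]] <- h$seq_plus
      }
    }
  }
  out
}

#' Tabulate per-cell, per-site methylation from aligned records
#'
#' For every annotated WCG/GCH/WCH site covered by at least one read,
#' counts reads supporting the unconverted base (methylated) against
#' reads supporting either state. Records are expected to be
#' deduplicated. A plus-strand record informs plus-strand cytosines:
#' read `C` at a reference `C` is methylated, read `T` unmethylated; any
#' other base is ignored at that site. Minus-strand records inform
#' minus-strand cytosines, which in plus orientation sit at reference
#' `G`: read `G` is methylated, read `A` unmethylated.
#'
#' @param records data.frame with `cell`, `chrom`, `start` (0-based),
#'   `strand`, `seq_plus` (plus-oriented sequence), as produced by
#'   [align_exact_bisulfite()] joined with demultiplexed cells.
#' @param contexts site annotation from [annotate_contexts()];
#'   `EXCLUDED` sites are never reported.
#' @return methylation-call table: data.frame `cell`, `chrom`, `pos`
#'   (1-based), `strand`, `context`, `meth`, `total` with `total >= 1`.
#' @export
call_sites <- function(records, contexts) {
  stopifnot(all(c("cell", "chrom", "start", "strand", "seq_plus") %in%
                  names(records)))
  keep_ctx <- contexts[contexts$context != "EXCLUDED", , drop = FALSE]
  ctx_key <- paste0(keep_ctx$chrom, ":", keep_ctx$pos, ":", keep_ctx$strand)
  ctx_lookup <- stats::setNames(seq_len(nrow(keep_ctx)), ctx_key)

  obs <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    bases <- strsplit(records$seq_plus[i], "", fixed = TRUE)[[1]]
    if (records$strand[i] == "+") {
      at <- which(bases %in% c("C", "T"))
      meth <- bases[at] == "C"
    } else {
      at <- which(bases %in% c("G", "A"))
      meth <- bases[at] == "G"
    }
    if (!length(at)) next
    obs[[i]] <- data.frame(
      cell = records$cell[i],
      key = paste0(records$chrom[i], ":", records$start[i] + at, ":",
                   records$strand[i]),
      meth = as.integer(meth),
      stringsAsFactors = FALSE
    )
  }
  obs <- do.call(rbind, obs)
  if (is.null(obs)) return(empty_call_table())
  site_idx <- ctx_lookup[obs$key]
  ok <- !is.na(site_idx)  # drops non-cytosine and EXCLUDED positions
  obs <- obs[ok, , drop = FALSE]
  site_idx <- site_idx[ok]
  if (!nrow(obs)) return(empty_call_table())
  grp <- paste0(obs$cell, "\r", site_idx)
  agg_meth <- rowsum(obs$meth, grp)
  agg_tot <- rowsum(rep(1L, nrow(obs)), grp)
  parts <- strsplit(rownames(agg_meth), "\r", fixed = TRUE)
  cell <- vapply(parts, `[`, character(1), 1L)
  idx <- as.integer(vapply(parts, `[`, character(1), 2L))
  out <- data.frame(
    cell = cell,
    chrom = keep_ctx$chrom[idx],
    pos = keep_ctx$pos[idx],
    strand = keep_ctx$strand[idx],
    context = keep_ctx$context[idx],
    meth = as.integer(agg_meth[, 1]),
    total = as.integer(agg_tot[, 1]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$cell, out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_call_table <- function() {
  data.frame(cell = character(0), chrom = character(0), pos = integer(0),
             strand = character(0), context = character(0),
             meth = integer(0), total = integer(0), stringsAsFactors = FALSE)
}

#' Per-cell quality-control statistics
#'
#' Global WCG% (mean per-site WCG methylation level x 100) summarises
#' endogenous CpG methylation; global GCH% summarises accessibility.
#' Bisulfite conversion efficiency is estimated from mitochondrial WCH
#' sites, which carry no biological methylation: conversion% =
#' 100 x (1 - pooled mitochondrial WCH methylation).
#'
#' @param calls methylation-call table ([call_sites()]).
#' @param mito_chromosome name of the mitochondrial chromosome
#'   (`NULL`: use all WCH sites, e.g. for synthetic genomes without a
#'   mitochondrial contig).
#' @return data.frame, one row per cell: `cell`, `n_wcg_sites`,
#'   `n_gch_sites`, `global_wcg_pct`, `global_gch_pct`,
#'   `conversion_rate_pct` (NA with a warning when no WCH calls exist).
#' @export
cell_qc <- function(calls, mito_chromosome = NULL) {
  cells <- sort(unique(calls$cell))
  out <- lapply(cells, function(cl) {
    tb <- calls[calls$cell == cl, , drop = FALSE]
    wcg <- tb[tb$context == "WCG", , drop = FALSE]
    gch <- tb[tb$context == "GCH", , drop = FALSE]
    wch <- tb[tb$context == "WCH", , drop = FALSE]
    if (!is.null(mito_chromosome)) {
      wch <- wch[wch$chrom == mito_chromosome, , drop = FALSE]
    }
    conv <- if (nrow(wch)) 100 * (1 - sum(wch$meth) / sum(wch$total)) else NA_real_
    data.frame(
      cell = cl,
      n_wcg_sites = nrow(wcg),
      n_gch_sites = nrow(gch),
      global_wcg_pct = if (nrow(wcg)) 100 * mean(wcg$meth / wcg$total) else NA_real_,
      global_gch_pct = if (nrow(gch)) 100 * mean(gch$meth / gch$total) else NA_real_,
      conversion_rate_pct = conv,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (any(is.na(out$conversion_rate_pct))) {
    warning("no WCH calls for some cells; conversion rate reported as NA")
  }
  out
}

#' Meta-profile of methylation around stranded features
#'
#' Averages per-cell methylation in fixed bins across a +/- flank around
#' feature anchors (e.g. transcription start sites), flipping
#' minus-strand features so that downstream always points right. Used to
#' visualise the canonical TSS signature: a WCG hypomethylation dip with
#' a GCH accessibility peak.
#'
#' @param calls methylation-call table.
#' @param features data.frame `chrom`, `pos` (1-based anchor),
#'   `strand`.
#' @param channel context class to profile (`"WCG"` or `"GCH"`).
#' @param flank half-window in bp (default 2000).
#' @param n_bins number of bins across the window (default 40).
#' @return data.frame `bin` (1..n_bins), `offset` (bp of bin centre
#'   relative to the anchor), `mean` (mean over cells of per-cell mean
#'   site methylation), `q25`, `q75`; bins no cell covers are `NA`.
#' @export
aggregate_profile <- function(calls, features, channel = "WCG",
                              flank = 2000L, n_bins = 40L) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(features)))
  tb <- calls[calls$context == channel, , drop = FALSE]
  bin_width <- 2 * flank / n_bins
  per_cell <- matrix(NA_real_, nrow = length(unique(tb$cell)), ncol = n_bins,
                     dimnames = list(sort(unique(tb$cell)), NULL))
  acc_sum <- matrix(0, nrow(per_cell), n_bins, dimnames = dimnames(per_cell))
  acc_n <- matrix(0L, nrow(per_cell), n_bins, dimnames = dimnames(per_cell))
  for (f in seq_len(nrow(features))) {
    sel <- tb$chrom == features$chrom[f] &
      abs(tb$pos - features$pos[f]) <= flank
    if (!any(sel)) next
    rel <- tb$pos[sel] - features$pos[f]
    if (features$strand[f] == "-") rel <- -rel
    bin <- pmin(n_bins, pmax(1L, floor((rel + flank) / bin_width) + 1L))
    lev <- tb$meth[sel] / tb$total[sel]
    cells <- tb$cell[sel]
    for (j in seq_along(bin)) {
      acc_sum[cells[j], bin[j]] <- acc_sum[cells[j], bin[j]] + lev[j]
      acc_n[cells[j], bin[j]] <- acc_n[cells[j], bin[j]] + 1L
    }
  }
  per_cell <- ifelse(acc_n > 0, acc_sum / acc_n, NA_real_)
  offset <- (seq_len(n_bins) - 0.5) * bin_width - flank
  data.frame(
    bin = seq_len(n_bins),
    offset = offset,
    mean = colMeans(per_cell, na.rm = TRUE),
    q25 = apply(per_cell, 2L, stats::quantile, probs = 0.25, na.rm = TRUE),
    q75 = apply(per_cell, 2L, stats::quantile, probs = 0.75, na.rm = TRUE)
  )
}
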