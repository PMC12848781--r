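#' Declarative read-1 layout for split-pool libraries
#'
#' Read 1 carries, at fixed offsets, `linker1 + barcodeB + linker2 +
#' barcodeA + genomic`. Linkers are matched by Hamming distance at their
#' fixed positions (no indel search — the structure is position-fixed by
#' the ligation chemistry); barcodes are corrected against whitelists by
#' Levenshtein distance.
#'
#' @param linker1,linker2 linker sequences.
#' @param barcode_length length of each ligation barcode.
#' @param whitelist_A,whitelist_B barcode whitelists for the two ligation
#'   rounds (plate A, default inventory 48; plate B, default 96).
#' @param linker_max_mismatch Hamming mismatches tolerated per linker.
#' @return object of class `read_layout` with segment offsets
#'   precomputed; `$genomic_offset` is the 0-based offset of the genomic
#'   suffix.
#' @export
read_layout <- function(linker1, linker2, barcode_length,
                        whitelist_A, whitelist_B,
                        linker_max_mismatch = 1L) {
  stopifnot(nchar(linker1) > 0, nchar(linker2) > 0, barcode_length > 0,
            length(whitelist_A) > 0, length(whitelist_B) > 0)
  l1 <- nchar(linker1); l2 <- nchar(linker2); bl <- as.integer(barcode_length)
  layout <- list(
    linker1 = linker1, linker2 = linker2,
    barcode_length = bl,
    whitelist_A = whitelist_A, whitelist_B = whitelist_B,
    linker_max_mismatch = as.integer(linker_max_mismatch),
    # 0-based offsets of each segment
    off_linker1 = 0L,
    off_barcode_B = l1,
    off_linker2 = l1 + bl,
    off_barcode_A = l1 + bl + l2,
    genomic_offset = l1 + bl + l2 + bl
  )
  class(layout) <- "read_layout"
  layout
}

#' Levenshtein edit distance
#'
#' Unit-cost insert/delete/substitute distance between two strings
#' (vectorised over `b`).
#'
#' @param a single string.
#' @param b character vector.
#' @return integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  as.integer(utils::adist(a, b))
}

#' Correct an observed barcode against a whitelist
#'
#' Returns the unique whitelist entry at minimum Levenshtein distance,
#' provided that minimum is at most 2 and is achieved by exactly one
#' entry; otherwise `NA` ("unknown barcode"). Barcodes further than 2
#' from every whitelist entry are discarded rather than guessed; ties at
#' the minimum are also discarded, since an ambiguous assignment risks
#' cross-contaminating cells.
#'
#' @param observed character vector of observed barcode sequences.
#' @param whitelist character vector of valid barcodes.
#' @param max_dist maximum correctable distance (default 2).
#' @return character vector: corrected barcode or `NA`.
#' @export
correct_barcode <- function(observed, whitelist, max_dist = 2L) {
  stopifnot(length(whitelist) > 0)
  d <- utils::adist(observed, whitelist)  # |observed| x |whitelist|
  out <- rep(NA_character_, length(observed))
  # exact hits short-circuit
  exact <- match(observed, whitelist)
  hit <- !is.na(exact)
  out[hit] <- whitelist[exact[hit]]
  todo <- which(!hit)
  if (length(todo)) {
    mins <- apply(d[todo, , drop = FALSE], 1L, min)
    for (i in seq_along(todo)) {
      if (mins[i] <= max_dist) {
        at <- which(d[todo[i], ] == mins[i])
        if (length(at) == 1L) out[todo[i]] <- whitelist[at]
      }
    }
  }
  out
}

#' Parse structured read-1 sequences against a layout
#'
#' Checks both linkers at their fixed offsets within the configured
#' Hamming tolerance; reads failing either check (or shorter than the
#' layout span) are flagged unknown-structure. Successful reads are
#' sliced into raw barcodes and the genomic suffix.
#'
#' @param seqs character vector of read-1 sequences.
#' @param layout a [read_layout()].
#' @return data.frame `ok` (logical; FALSE = unknown structure),
#'   `barcode_A_raw`, `barcode_B_raw`, `genomic`.
#' @export
parse_read <- function(seqs, layout) {
  stopifnot(inherits(layout, "read_layout"))
  n <- length(seqs)
  span <- layout$genomic_offset
  long_enough <- nchar(seqs) > span
  sub0 <- function(off, len) substring(seqs, off + 1L, off + len)
  obs_l1 <- sub0(layout$off_linker1, nchar(layout$linker1))
  obs_l2 <- sub0(layout$off_linker2, nchar(layout$linker2))
  mm1 <- hamming_vec(obs_l1, layout$linker1)
  mm2 <- hamming_vec(obs_l2, layout$linker2)
  ok <- long_enough & mm1 <= layout$linker_max_mismatch &
    mm2 <= layout$linker_max_mismatch
  data.frame(
    ok = ok,
    barcode_A_raw = ifelse(ok, sub0(layout$off_barcode_A, layout$barcode_length), NA),
    barcode_B_raw = ifelse(ok, sub0(layout$off_barcode_B, layout$barcode_length), NA),
    genomic = ifelse(ok, substring(seqs, span + 1L), NA),
    stringsAsFactors = FALSE
  )
}

# Hamming distance of many strings against one pattern of equal length
hamming_vec <- function(obs, pattern) {
  pv <- strsplit(pattern, "", fixed = TRUE)[[1]]
  k <- length(pv)
  out <- rep(k, length(obs))
  full <- nchar(obs) == k
  if (any(full)) {
    m <- matrix(unlist(strsplit(obs[full], "", fixed = TRUE)),
                nrow = k)
    out[full] <- colSums(m != pv)
  }
  out
}

#' Demultiplex structured reads into cells
#'
#' Parses each read 1 against the layout, corrects both barcodes against
#' their whitelists (independently, at Levenshtein distance <= 2), and
#' assigns reads to cells identified by (barcode A, barcode B, PCR
#' index). Every read ends up in exactly one of three bins — assigned,
#' unknown-structure, or unknown-barcode — so the report counters always
#' reconcile to the input total.
#'
#' @param reads data.frame with columns `read_id`, `seq1`, and
#'   optionally `pcr_index` (defaults to `"PCR01"`); extra columns pass
#'   through.
#' @param layout a [read_layout()].
#' @return list with
#'   * `assigned`: data.frame `read_id`, `cell` (`"<A>_<B>_<index>"`),
#'     `barcode_A`, `barcode_B`, `pcr_index`, `genomic`;
#'   * `report`: list `n_total`, `n_unknown_structure`,
#'     `n_unknown_barcode`, `n_assigned`, `per_cell_counts`,
#'     `n_duplicates_removed` (0 until [dedup_records()]).
#' @export
demultiplex <- function(reads, layout) {
  stopifnot(is.data.frame(reads), all(c("read_id", "seq1") %in% names(reads)))
  pcr <- if ("pcr_index" %in% names(reads)) reads$pcr_index else rep("PCR01", nrow(reads))
  parsed <- parse_read(reads$seq1, layout)
  n_total <- nrow(reads)
  n_bad_struct <- sum(!parsed$ok)
  idx <- which(parsed$ok)
  bcA <- correct_barcode(parsed$barcode_A_raw[idx], layout$whitelist_A)
  bcB <- correct_barcode(parsed$barcode_B_raw[idx], layout$whitelist_B)
  good <- !is.na(bcA) & !is.na(bcB)
  n_bad_bc <- sum(!good)
  keep <- idx[good]
  assigned <- data.frame(
    read_id = reads$read_id[keep],
    cell = paste(bcA[good], bcB[good], pcr[keep], sep = "_"),
    barcode_A = bcA[good],
    barcode_B = bcB[good],
    pcr_index = pcr[keep],
    genomic = parsed$genomic[keep],
    stringsAsFactors = FALSE
  )
  per_cell <- table(assigned$cell)
  report <- list(
    n_total = n_total,
    n_unknown_structure = n_bad_struct,
    n_unknown_barcode = n_bad_bc,
    n_assigned = nrow(assigned),
    per_cell_counts = as.list(per_cell),
    n_duplicates_removed = 0L
  )
  stopifnot(report$n_total == report$n_unknown_structure +
              report$n_unknown_barcode + report$n_assigned)
  list(assigned = assigned, report = report)
}

#' Remove PCR duplicates within cells by genomic coordinate
#'
#' Within each cell, aligned records sharing (chromosome, start, strand)
#' collapse to the first record in input order; identical coordinates in
#' different cells are kept (barcode-aware duplicate marking).
#'
#' @param records data.frame with columns `cell`, `chrom`, `start`,
#'   `strand` (extra columns pass through).
#' @return list `records` (survivors, input order preserved) and
#'   `n_removed`.
#' @export
dedup_records <- function(records) {
  stopifnot(all(c("cell", "chrom", "start", "strand") %in% names(records)))
  key <- paste(records$cell, records$chrom, records$start, records$strand,
               sep = "\r")
  keep <- !duplicated(key)
  list(records = records[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Classify cells in a species-mixing (barnyard) experiment
#'
#' Cells whose reads map overwhelmingly to one genome are called for
#' that species; cells with mixed mappings are collisions (two cells
#' sharing one barcode combination). The threshold comparison is `>=`,
#' so a cell exactly at the purity threshold is called for the species.
#'
#' @param counts_a,counts_b per-cell read counts mapped to genome A / B
#'   (equal-length named or unnamed vectors).
#' @param purity_threshold minimum fraction of reads on one genome
#'   (default 0.9).
#' @param min_reads cells with fewer total reads are excluded
#'   (default 1000).
#' @return data.frame `label` (`"speciesA"`, `"speciesB"`,
#'   `"collision"`, or `"excluded"`), `frac_a`, `total`.
#' @export
species_mix_classify <- function(counts_a, counts_b,
                                 purity_threshold = 0.9,
                                 min_reads = 1000L) {
  stopifnot(length(counts_a) == length(counts_b))
  total <- counts_a + counts_b
  frac_a <- ifelse(total > 0, counts_a / total, NA_real_)
  label <- rep("collision", length(total))
  label[!is.na(frac_a) & frac_a >= purity_threshold] <- "speciesA"
  label[!is.na(frac_a) & (1 - frac_a) >= purity_threshold] <- "speciesB"
  label[total < min_reads] <- "excluded"
  data.frame(label = label, frac_a = frac_a, total = total,
             stringsAsFactors = FALSE,
             row.names = names(counts_a))
}

#' Expected per-cell barcode collision rate
#'
#' Probability that a given cell shares its two-round barcode
#' combination with at least one other of the `n` cells in its tube,
#' when each cell draws one of `B` combinations uniformly:
#' `1 - (1 - 1/B)^(n-1)`. Strictly increasing in `n` and decreasing in
#' `B` — more cells per tube, or fewer combinations, mean more doublets.
#'
#' With the default two-plate inventory, B = 48 x 96 = 4608; at 200
#' cells per tube the rate stays below 5%.
#'
#' @param n_cells_per_tube cells pooled per tube (>= 1).
#' @param n_combinations barcode combinations available (default 4608).
#' @return collision probability.
#' @seealso [simulate_collision_rate()] for the Monte-Carlo counterpart.
#' @export
expected_collision_rate <- function(n_cells_per_tube,
                                    n_combinations = 48L * 96L) {
  stopifnot(n_cells_per_tube >= 1, n_combinations >= 1)
  1 - (1 - 1 / n_combinations)^(n_cells_per_tube - 1)
}

#' Monte-Carlo per-cell collision rate
#'
#' Randomly assigns `n_cells_per_tube` cells to `n_combinations` barcode
#' combinations and measures the fraction of cells landing in a
#' multiply-occupied combination, averaged over replicates.
#'
#' @inheritParams expected_collision_rate
#' @param n_reps Monte-Carlo replicates.
#' @param seed integer seed.
#' @return list `rate` (mean collision fraction), `se` (standard error
#'   over replicates), `n_reps`.
#' @export
simulate_collision_rate <- function(n_cells_per_tube,
                                    n_combinations = 48L * 96L,
                                    n_reps = 10000L, seed = 1L) {
  withr_seed(seed, {
    rates <- vapply(seq_len(n_reps), function(i) {
      combo <- sample.int(n_combinations, n_cells_per_tube, replace = TRUE)
      occ <- tabulate(combo, nbins = n_combinations)
      sum(occ[occ > 1L]) / n_cells_per_tube
    }, numeric(1))
  })
  list(rate = mean(rates), se = stats::sd(rates) / sqrt(n_reps),
       n_reps = n_reps)
}
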