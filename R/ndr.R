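#' Pool per-cell methylation calls into a pseudo-bulk sample
#'
#' Site-level counts are summed over the member cells; the pooled site
#' set is the union. Pooling is additive and permutation-invariant, so a
#' singleton group returns the cell's own table.
#'
#' @param calls methylation-call table ([call_sites()]).
#' @param cells character vector of member cells (`NULL` = all).
#' @param context optional context filter (e.g. `"GCH"`).
#' @return data.frame `chrom`, `pos`, `strand`, `context`, `meth`,
#'   `total` (no `cell` column).
#' @export
pseudo_bulk <- function(calls, cells = NULL, context = NULL) {
  tb <- calls
  if (!is.null(cells)) {
    if (!length(cells)) stop("cell group is empty")
    tb <- tb[tb$cell %in% cells, , drop = FALSE]
  }
  if (!is.null(context)) tb <- tb[tb$context %in% context, , drop = FALSE]
  if (!nrow(tb)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      meth = integer(0), total = integer(0)))
  }
  key <- paste(tb$chrom, tb$pos, tb$strand, tb$context, sep = "\r")
  meth <- rowsum(tb$meth, key)
  total <- rowsum(tb$total, key)
  parts <- strsplit(rownames(meth), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    strand = vapply(parts, `[`, character(1), 3L),
    context = vapply(parts, `[`, character(1), 4L),
    meth = as.integer(meth[, 1]),
    total = as.integer(total[, 1]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pearson chi-square on the 2x2 table [[a, b], [c, d]], df = 1, no
# continuity correction. This is the window-vs-background test at the
# heart of NDR calling, so it is written out rather than delegated;
# stats::pchisq supplies the tail probability.
pearson_chi2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  num <- n * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(den > 0, num / den, 0)
  chi2
}

#' Sliding-window chi-square scan of pseudo-bulk GpC methylation
#'
#' Tiles each chromosome with fixed windows (default 100 bp, step
#' 20 bp, anchored at coordinate 0), aggregates GCH calls per window,
#' and tests the window's methylated/unmethylated split against the
#' chromosomal background (the chromosome totals minus the window's own
#' counts, so a window never tests against itself) with a Pearson
#' chi-square on the 2x2 table, 1 df, no continuity correction.
#' Trailing partial windows are emitted like any other; windows with no
#' GCH calls are dropped.
#'
#' @param pooled pseudo-bulk GCH table ([pseudo_bulk()] with
#'   `context = "GCH"`).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param window,step window and step length in bp.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `n_gch_sites`, `meth`, `total`, `bg_meth`, `bg_total`, `chi2`, `p`.
#' @export
window_scan <- function(pooled, chrom_lengths, window = 100L, step = 20L) {
  stopifnot(window >= step)
  out <- vector("list", length(chrom_lengths))
  for (ci in seq_along(chrom_lengths)) {
    chrom <- names(chrom_lengths)[ci]
    tb <- pooled[pooled$chrom == chrom, , drop = FALSE]
    if (!nrow(tb)) {
      warning("chromosome ", chrom, " has no GCH calls; skipped")
      next
    }
    len <- chrom_lengths[[ci]]
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    chrom_meth <- sum(tb$meth)
    chrom_total <- sum(tb$total)
    # assign each site (0-based site coordinate pos-1) to all overlapping
    # windows: window k covers [k*step, k*step + window)
    pos0 <- tb$pos - 1L
    first_w <- pmax(0L, ceiling((pos0 - window + 1L) / step))
    last_w <- pos0 %/% step
    reps <- last_w - first_w + 1L
    widx <- sequence(reps, from = first_w) + 1L  # 1-based window index
    site_of <- rep(seq_len(nrow(tb)), reps)
    keep <- widx <= length(starts)
    widx <- widx[keep]; site_of <- site_of[keep]
    w_meth <- rowsum(tb$meth[site_of], widx)
    w_total <- rowsum(tb$total[site_of], widx)
    w_sites <- rowsum(rep(1L, length(site_of)), widx)
    wi <- as.integer(rownames(w_meth))
    a <- w_meth[, 1]; ta <- w_total[, 1]
    c_ <- chrom_meth - a; d_ <- (chrom_total - ta) - c_
    chi2 <- pearson_chi2(a, ta - a, c_, d_)
    p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
    out[[ci]] <- data.frame(
      chrom = chrom,
      start = starts[wi],
      end = pmin(starts[wi] + window, len),
      n_gch_sites = as.integer(w_sites[, 1]),
      meth = as.integer(a),
      total = as.integer(ta),
      bg_meth = as.integer(c_),
      bg_total = as.integer(chrom_total - ta),
      chi2 = chi2,
      p = p,
      stringsAsFactors = FALSE
    )
    out[[ci]] <- out[[ci]][order(out[[ci]]$start), , drop = FALSE]
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Filter scanned windows to significant accessible windows
#'
#' Keeps windows that pass all of: p below the significance cutoff,
#' more than `min_sites` GCH sites (strictly more — a window with
#' exactly `min_sites` is rejected), total coverage of at least one
#' read, and — because nucleosome-depleted regions are by construction
#' GpC-hypermethylated — window methylation proportion above the
#' background proportion. The direction filter can be switched off to
#' also retrieve hyper-protected windows.
#'
#' @param windows output of [window_scan()].
#' @param p_max significance cutoff (default 1e-10; windows with
#'   `p < p_max` are kept).
#' @param min_sites windows must contain strictly more GCH sites
#'   (default 5).
#' @param min_coverage minimum total GCH call count (default 1).
#' @param direction `"above_background"` (default) or `"both"`.
#' @return the significant subset of `windows`.
#' @export
filter_windows <- function(windows, p_max = 1e-10, min_sites = 5L,
                           min_coverage = 1L,
                           direction = c("above_background", "both")) {
  direction <- match.arg(direction)
  keep <- windows$p < p_max &
    windows$n_gch_sites > min_sites &
    windows$total >= min_coverage
  if (direction == "above_background") {
    keep <- keep & (windows$meth / windows$total >
                      windows$bg_meth / pmax(1L, windows$bg_total))
  }
  windows[keep & !is.na(keep), , drop = FALSE]
}

#' Merge significant windows into nucleosome-depleted regions
#'
#' Overlapping or book-ended windows merge into one region (the
#' behaviour of the canonical BED interval-merge). Each region records
#' how many windows it absorbed, its smallest window p-value, and the
#' coverage-weighted mean GCH methylation of its constituents.
#'
#' @param windows significant windows ([filter_windows()]).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open,
#'   sorted, pairwise disjoint), `n_windows_merged`, `min_p`,
#'   `mean_gch_meth`.
#' @export
merge_ndrs <- function(windows) {
  if (!nrow(windows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows_merged = integer(0),
                      min_p = numeric(0), mean_gch_meth = numeric(0)))
  }
  gr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$start + 1L, end = windows$end)
  )
  merged <- GenomicRanges::reduce(gr)  # book-ended intervals coalesce
  ov <- GenomicRanges::findOverlaps(gr, merged)
  grp <- S4Vectors::subjectHits(ov)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = BiocGenerics::start(merged) - 1L,
    end = BiocGenerics::end(merged),
    n_windows_merged = as.integer(tabulate(grp, nbins = length(merged))),
    min_p = as.numeric(tapply(windows$p[S4Vectors::queryHits(ov)], grp, min)),
    mean_gch_meth = as.numeric(
      tapply(windows$meth[S4Vectors::queryHits(ov)], grp, sum) /
        tapply(windows$total[S4Vectors::queryHits(ov)], grp, sum)
    ),
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Call nucleosome-depleted regions from pseudo-bulk GCH calls
#'
#' Convenience wrapper: [window_scan()] then [filter_windows()] then
#' [merge_ndrs()].
#'
#' @inheritParams window_scan
#' @inheritParams filter_windows
#' @return list `ndrs` (merged regions), `windows` (all scanned
#'   windows), `significant` (the kept subset).
#' @export
call_ndrs <- function(pooled, chrom_lengths, window = 100L, step = 20L,
                      p_max = 1e-10, min_sites = 5L, min_coverage = 1L,
                      direction = "above_background") {
  windows <- window_scan(pooled, chrom_lengths, window = window, step = step)
  sig <- filter_windows(windows, p_max = p_max, min_sites = min_sites,
                        min_coverage = min_coverage, direction = direction)
  list(ndrs = merge_ndrs(sig), windows = windows, significant = sig)
}

#' Evaluate called regions against planted truth intervals
#'
#' Recall is the fraction of truth intervals overlapped by at least one
#' call; precision the fraction of calls overlapping truth. Boundary
#' error is measured per recovered truth interval against the union
#' span of its overlapping calls (a region split by a sparse-site gap
#' still recovers both outer boundaries).
#'
#' @param called,truth data.frames with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return list `recall`, `precision`, `boundary_errors` (per recovered
#'   truth interval, max of |start error|, |end error| in bp),
#'   `n_called`, `n_truth`.
#' @export
evaluate_ndr_calls <- function(called, truth) {
  as_gr <- function(x) GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(start = x$start + 1L, end = x$end))
  gc <- as_gr(called); gt <- as_gr(truth)
  ov <- GenomicRanges::findOverlaps(gt, gc)
  recall <- mean(seq_along(gt) %in% S4Vectors::queryHits(ov))
  precision <- if (length(gc)) {
    mean(seq_along(gc) %in% S4Vectors::subjectHits(ov))
  } else NA_real_
  berr <- vapply(unique(S4Vectors::queryHits(ov)), function(i) {
    hits <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    max(abs(min(BiocGenerics::start(gc)[hits]) - BiocGenerics::start(gt)[i]),
        abs(max(BiocGenerics::end(gc)[hits]) - BiocGenerics::end(gt)[i]))
  }, numeric(1))
  list(recall = recall, precision = precision, boundary_errors = berr,
       n_called = length(gc), n_truth = length(gt))
}

#' Write regions as BED6
#'
#' Score is `-log10(min_p)` capped at 1000; strand is `"."`.
#'
#' @param ndrs merged regions ([merge_ndrs()]).
#' @param path output file.
#' @export
write_ndr_bed <- function(ndrs, path) {
  if (!nrow(ndrs)) {
    file.create(path)
    return(invisible(path))
  }
  score <- pmin(1000, round(-log10(pmax(ndrs$min_p, 1e-300)), 2))
  bed <- data.frame(ndrs$chrom, ndrs$start, ndrs$end,
                    sprintf("NDR_%d", seq_len(nrow(ndrs))),
                    score, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
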