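#' Count aligned reads in fixed genomic windows
#'
#' Tiles each chromosome with half-open fixed-size windows (default
#' 1 Mb) and counts deduplicated records per entity (cell, or
#' pseudo-bulk clone when `group_of` is given — pseudo-bulk counts are
#' the sums over member cells). A read whose start sits exactly on a
#' window boundary belongs to the right-hand window.
#'
#' @param records data.frame `cell`, `chrom`, `start` (0-based).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param window window size in bp (default 1e6).
#' @param group_of optional named vector cell -> group; counts are then
#'   per group.
#' @return list `counts` (entities x windows integer matrix), `windows`
#'   (data.frame `chrom`, `start`, `end`).
#' @export
window_counts <- function(records, chrom_lengths, window = 1000000L,
                          group_of = NULL) {
  windows <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq.int(0L, max(0L, chrom_lengths[[ch]] - 1L), by = window)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window, chrom_lengths[[ch]]),
               stringsAsFactors = FALSE)
  }))
  win_id <- paste0(windows$chrom, ":", as.integer(windows$start) %/% window)
  entity <- if (is.null(group_of)) records$cell else as.character(group_of[records$cell])
  entities <- sort(unique(entity))
  counts <- matrix(0L, length(entities), nrow(windows),
                   dimnames = list(entities, win_id))
  key <- paste0(records$chrom, ":", as.integer(records$start) %/% window)
  tab <- table(factor(entity, levels = entities),
               factor(key, levels = win_id))
  counts[] <- as.integer(tab)
  list(counts = counts, windows = windows)
}

#' Copy-ratio profiles from window counts
#'
#' Normalizes each entity's window counts to its total, divides by the
#' same quantity for a diploid reference profile, and scales by the
#' ploidy to integer copy-number calls: `ratio = 1` is diploid,
#' `copy_number = round(ploidy x ratio)`. Windows where the reference
#' has zero counts are masked (`NA`) and excluded from the per-entity
#' coefficient of variation `cv = sd(ratio)/mean(ratio)`, which
#' summarises genomic instability. When no reference is supplied the
#' median per-window profile across entities is used — the standard
#' single-cell fallback when most cells are diploid.
#'
#' This is a deliberately simple read-depth caller (no GC/mappability
#' correction, no segmentation); it resolves clone-scale gains and
#' losses at megabase windows.
#'
#' @param wc output of [window_counts()].
#' @param reference_counts integer vector over the same windows (e.g. a
#'   normal pseudo-bulk), or `NULL` for the median profile.
#' @param ploidy reference ploidy (default 2).
#' @param rescale_median re-anchor each entity's diploid baseline by
#'   dividing its ratios by their median (default TRUE). Without it, an
#'   entity's own amplified segments deflate all its ratios through the
#'   total-count normalization; with it, a gain of one chromosome among
#'   many reads out at its true copy ratio. Assumes the majority of
#'   windows are at reference ploidy.
#' @return object of class `cnv_profile`: list `ratio` (entities x
#'   windows), `copy_number`, `cv` (named vector), `windows`, `ploidy`.
#' @export
copy_ratio <- function(wc, reference_counts = NULL, ploidy = 2L,
                       rescale_median = TRUE) {
  counts <- wc$counts
  if (any(rowSums(counts) == 0)) stop("entities with zero total counts")
  if (is.null(reference_counts)) {
    reference_counts <- apply(counts, 2L, stats::median)
  }
  stopifnot(length(reference_counts) == ncol(counts))
  ref_frac <- reference_counts / sum(reference_counts)
  mask <- reference_counts > 0
  frac <- counts / rowSums(counts)
  ratio <- sweep(frac, 2L, ref_frac, "/")
  ratio[, !mask] <- NA_real_
  if (rescale_median) {
    med <- apply(ratio, 1L, stats::median, na.rm = TRUE)
    ratio <- ratio / med
  }
  cn <- round(ploidy * ratio)
  cv <- apply(ratio, 1L, function(r) {
    r <- r[!is.na(r)]
    stats::sd(r) / mean(r)
  })
  structure(list(ratio = ratio, copy_number = cn, cv = cv,
                 windows = wc$windows, ploidy = ploidy),
            class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("cnv_profile: %d entities x %d windows (ploidy %d)\n",
              nrow(x$ratio), ncol(x$ratio), x$ploidy))
  cat("cv range:", sprintf("%.3f", range(x$cv)), "\n")
  invisible(x)
}

#' Cluster entities into clones by their copy-ratio profiles
#'
#' Hierarchical clustering (Euclidean distance, Ward linkage) of ratio
#' vectors, cut at `k` clones. Masked windows are dropped before
#' clustering.
#'
#' @param profile a `cnv_profile`.
#' @param k number of clones.
#' @return named integer vector: entity -> clone.
#' @export
cluster_clones <- function(profile, k) {
  r <- profile$ratio
  r <- r[, colSums(is.na(r)) == 0, drop = FALSE]
  hc <- stats::hclust(stats::dist(r), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Average copy ratios to a coarser display resolution
#'
#' @param profile a `cnv_profile`.
#' @param factor how many adjacent windows to average (e.g. 10 to view
#'   1-Mb calls at 10 Mb).
#' @return list `ratio` (entities x coarse windows), `windows`.
#' @export
coarsen_profile <- function(profile, factor = 10L) {
  w <- profile$windows
  grp <- paste0(w$chrom, ":", w$start %/% (factor * (w$end[1] - w$start[1])))
  grp <- factor(grp, levels = unique(grp))
  ratio <- t(apply(profile$ratio, 1L, function(r) {
    tapply(r, grp, mean, na.rm = TRUE)
  }))
  starts <- tapply(w$start, grp, min)
  ends <- tapply(w$end, grp, max)
  chroms <- tapply(w$chrom, grp, `[`, 1L)
  list(ratio = ratio,
       windows = data.frame(chrom = as.character(chroms),
                            start = as.integer(starts),
                            end = as.integer(ends)))
}
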