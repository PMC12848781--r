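#' Build a cells x genomic-bin methylation matrix
#'
#' Each chromosome is tiled with fixed-size non-overlapping bins
#' (default 250 kb). The value of (cell, bin) is the mean over covered
#' sites of the per-site methylation level; bins with no covered site
#' are missing (`NA`), never zero. A 1-based site position `pos` maps to
#' bin `floor((pos - 1) / bin_size)`.
#'
#' @param calls methylation-call table ([call_sites()]).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param bin_size bin width in bp (default 250000).
#' @param channel context class (`"WCG"` or `"GCH"`).
#' @return object of class `bin_matrix`: list with `values` (cells x
#'   bins numeric matrix with `NA` for missing), `bins` (data.frame
#'   `chrom`, `start`, `end`), `channel`, `bin_size`.
#' @export
build_bin_matrix <- function(calls, chrom_lengths, bin_size = 250000L,
                             channel = "WCG") {
  tb <- calls[calls$context == channel, , drop = FALSE]
  bins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq.int(0L, max(0L, chrom_lengths[[ch]] - 1L), by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, chrom_lengths[[ch]]),
               stringsAsFactors = FALSE)
  }))
  bin_id <- paste0(bins$chrom, ":", bins$start)
  cells <- sort(unique(tb$cell))
  values <- matrix(NA_real_, length(cells), nrow(bins),
                   dimnames = list(cells, bin_id))
  if (nrow(tb)) {
    b <- (tb$pos - 1L) %/% bin_size * bin_size
    key <- paste0(tb$chrom, ":", b)
    lev <- tb$meth / tb$total
    grp <- paste0(tb$cell, "\r", key)
    sums <- rowsum(lev, grp)
    ns <- rowsum(rep(1L, nrow(tb)), grp)
    parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
    ci <- match(vapply(parts, `[`, character(1), 1L), cells)
    bi <- match(vapply(parts, `[`, character(1), 2L), bin_id)
    values[cbind(ci, bi)] <- sums[, 1] / ns[, 1]
  }
  structure(list(values = values, bins = bins, channel = channel,
                 bin_size = as.integer(bin_size)),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("bin_matrix: %d cells x %d bins (%s, %d bp bins), %.1f%% observed\n",
              nrow(x$values), ncol(x$values), x$channel, x$bin_size,
              100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Filter a bin matrix by cell and bin coverage
#'
#' Cells are filtered first, then bins: cells covering fewer than
#' `min_bins_per_cell` bins are removed (strictly fewer — a cell at
#' exactly the threshold is kept), then bins observed in less than
#' `min_cell_fraction_per_bin` of the remaining cells are removed
#' (strictly less — a bin at exactly the fraction is kept).
#' Re-applying the filter to its own output changes nothing.
#'
#' @param m a `bin_matrix`.
#' @param min_bins_per_cell minimum covered bins per cell
#'   (default 10000).
#' @param min_cell_fraction_per_bin minimum fraction of cells covering
#'   a bin (default 0.5).
#' @return the filtered `bin_matrix`.
#' @export
filter_matrix <- function(m, min_bins_per_cell = 10000L,
                          min_cell_fraction_per_bin = 0.5) {
  obs <- !is.na(m$values)
  keep_cells <- rowSums(obs) >= min_bins_per_cell
  if (!any(keep_cells)) {
    stop(sprintf("no cells left: all %d cells cover < %d bins",
                 nrow(m$values), min_bins_per_cell))
  }
  v <- m$values[keep_cells, , drop = FALSE]
  keep_bins <- colMeans(!is.na(v)) >= min_cell_fraction_per_bin
  if (!any(keep_bins)) {
    stop(sprintf("no bins left after cell filter (%d cells kept)", nrow(v)))
  }
  m$values <- v[, keep_bins, drop = FALSE]
  m$bins <- m$bins[keep_bins, , drop = FALSE]
  m
}

#' Impute missing bins with each cell's mean methylation
#'
#' Missing (cell, bin) entries are replaced by that cell's mean over its
#' observed bins; observed values are untouched, so each cell's mean is
#' preserved exactly.
#'
#' @param m a `bin_matrix` (every cell must have at least one observed
#'   bin).
#' @return dense numeric matrix (cells x bins).
#' @export
impute_mean <- function(m) {
  v <- m$values
  cm <- rowMeans(v, na.rm = TRUE)
  if (any(!is.finite(cm))) stop("cells with no observed bins cannot be imputed")
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- cm[idx[, 1]]
  v
}

#' Embed and cluster cells from a dense bin matrix
#'
#' Centred PCA (top `n_pcs` components, capped at min(cells, bins) - 1),
#' a k-nearest-neighbour graph on the component scores, Leiden community
#' detection, and a UMAP layout — all under a fixed seed.
#'
#' @param dense dense cells x bins matrix ([impute_mean()]).
#' @param n_pcs number of principal components (default 50).
#' @param k neighbours for the kNN graph (default 15).
#' @param resolution Leiden resolution (default 1.0).
#' @param seed integer seed for Leiden and UMAP.
#' @return list `pcs` (cells x components), `cluster_labels` (named
#'   integer vector), `umap_xy` (cells x 2).
#' @export
embed_and_cluster <- function(dense, n_pcs = 50L, k = 15L,
                              resolution = 1.0, seed = 1L) {
  n <- nrow(dense)
  if (n < 3L) stop("need at least 3 cells")
  n_pcs <- min(n_pcs, n - 1L, ncol(dense))
  pca <- stats::prcomp(dense, center = TRUE, scale. = FALSE, rank. = n_pcs)
  pcs <- pca$x
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(pcs))
  diag(d) <- Inf
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    cbind(i, nb)
  }))
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  withr_seed(seed, {
    comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = resolution, n_iterations = 5L)
  })
  labels <- igraph::membership(comm)
  names(labels) <- rownames(dense)
  umap_xy <- uwot::umap(pcs, n_neighbors = min(15L, n - 1L),
                        seed = seed, n_threads = 1L)
  rownames(umap_xy) <- rownames(dense)
  list(pcs = pcs, cluster_labels = labels, umap_xy = umap_xy)
}

#' Promoter-level methylation by cell group
#'
#' Pools counts over all sites in each promoter window and all cells of
#' a group (sum of methylated over sum of total — robust to sparse
#' per-cell coverage; a mean-of-per-cell-ratios alternative is
#' available), then tabulates per-gene differences of each group
#' against a reference group, sortable by absolute difference.
#'
#' @param calls methylation-call table.
#' @param promoters data.frame `gene`, `chrom`, `start`, `end` (0-based
#'   half-open, e.g. TSS +/- 1 kb), `strand`.
#' @param groups named character/integer vector: cell -> group label.
#' @param reference_group group the others are compared against
#'   (default: first level).
#' @param channel context class (default `"WCG"`).
#' @param method `"pooled"` (default) or `"mean_of_cells"`.
#' @return list `levels` (genes x groups matrix of methylation levels,
#'   `NA` where a group has no coverage), `differences` (data.frame
#'   `gene`, `group`, `level`, `reference_level`, `delta`, sorted by
#'   `|delta|` descending).
#' @export
promoter_methylation <- function(calls, promoters, groups,
                                 reference_group = NULL,
                                 channel = "WCG",
                                 method = c("pooled", "mean_of_cells")) {
  method <- match.arg(method)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(promoters)))
  tb <- calls[calls$context == channel & calls$cell %in% names(groups), ,
              drop = FALSE]
  tb$group <- as.character(groups[tb$cell])
  group_names <- unique(as.character(groups))
  if (is.null(reference_group)) reference_group <- group_names[1]
  lev <- matrix(NA_real_, nrow(promoters), length(group_names),
                dimnames = list(promoters$gene, group_names))
  for (i in seq_len(nrow(promoters))) {
    sel <- tb$chrom == promoters$chrom[i] &
      tb$pos - 1L >= promoters$start[i] & tb$pos - 1L < promoters$end[i]
    if (!any(sel)) next
    sub <- tb[sel, , drop = FALSE]
    for (g in group_names) {
      sg <- sub[sub$group == g, , drop = FALSE]
      if (!nrow(sg)) next
      lev[i, g] <- if (method == "pooled") {
        sum(sg$meth) / sum(sg$total)
      } else {
        cellmeans <- tapply(sg$meth / sg$total, sg$cell, mean)
        mean(cellmeans)
      }
    }
  }
  others <- setdiff(group_names, reference_group)
  diffs <- do.call(rbind, lapply(others, function(g) {
    data.frame(gene = promoters$gene, group = g, level = lev[, g],
               reference_level = lev[, reference_group],
               delta = lev[, g] - lev[, reference_group],
               stringsAsFactors = FALSE)
  }))
  if (is.null(diffs)) {
    diffs <- data.frame(gene = character(0), group = character(0),
                        level = numeric(0), reference_level = numeric(0),
                        delta = numeric(0))
  }
  diffs <- diffs[order(-abs(diffs$delta)), , drop = FALSE]
  rownames(diffs) <- NULL
  list(levels = lev, differences = diffs)
}
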