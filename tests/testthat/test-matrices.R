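mk_matrix <- function(values, bin_size = 1000L) {
  bins <- data.frame(chrom = "chr1",
                     start = (seq_len(ncol(values)) - 1L) * bin_size,
                     end = seq_len(ncol(values)) * bin_size)
  structure(list(values = values, bins = bins, channel = "WCG",
                 bin_size = bin_size), class = "bin_matrix")
}

test_that("bin values are means of site levels and absence stays missing", {
  calls <- data.frame(
    cell = "c1", chrom = "chr1",
    pos = c(100L, 200L, 1500L), strand = "+", context = "WCG",
    meth = c(1L, 2L, 3L), total = c(5L, 5L, 3L)
  )
  m <- build_bin_matrix(calls, c(chr1 = 3000L), bin_size = 1000L)
  expect_equal(m$values["c1", "chr1:0"], mean(c(0.2, 0.4)))
  expect_equal(m$values["c1", "chr1:1000"], 1)
  expect_true(is.na(m$values["c1", "chr1:2000"]))
  # 1-based position exactly at a bin-size multiple belongs to the earlier
  # bin: floor((250000 - 1)/250000) = 0
  calls2 <- data.frame(cell = "c1", chrom = "chr1", pos = 250000L,
                       strand = "+", context = "WCG", meth = 1L, total = 1L)
  m2 <- build_bin_matrix(calls2, c(chr1 = 500000L), bin_size = 250000L)
  expect_equal(unname(m2$values[1, ]), c(1, NA))
})

test_that("matrix filters use strict-less boundaries, cells before bins", {
  set.seed(61)
  n_bins <- 10500L
  v <- matrix(runif(4 * n_bins), nrow = 4,
              dimnames = list(paste0("c", 1:4), NULL))
  # cell c1 covers 9999 bins -> dropped; c2 covers exactly 10000 -> kept
  v[1, 10000:n_bins] <- NA
  v[2, 10001:n_bins] <- NA
  m <- mk_matrix(v)
  f <- filter_matrix(m, min_bins_per_cell = 10000L,
                     min_cell_fraction_per_bin = 0.5)
  expect_false("c1" %in% rownames(f$values))
  expect_true("c2" %in% rownames(f$values))
  # bin coverage boundary on the remaining 3 cells: a bin observed in 1/3
  # of cells (<50%) is dropped; one at exactly 2/3 >= 50% is kept
  expect_false(any(colMeans(!is.na(f$values)) < 0.5))
  v2 <- matrix(runif(4 * 20), nrow = 4,
               dimnames = list(paste0("c", 1:4), NULL))
  v2[1:2, 1] <- NA   # bin 1 at exactly 50% -> kept
  v2[1:3, 2] <- NA   # bin 2 at 25% -> dropped
  f2 <- filter_matrix(mk_matrix(v2), min_bins_per_cell = 1L,
                      min_cell_fraction_per_bin = 0.5)
  expect_equal(ncol(f2$values), 19L)
  expect_true(0L %in% f2$bins$start)       # 50% bin kept
  expect_false(1000L %in% f2$bins$start)   # 25% bin dropped
  # idempotence and dense identity
  f3 <- filter_matrix(f2, min_bins_per_cell = 1L,
                      min_cell_fraction_per_bin = 0.5)
  expect_identical(f2, f3)
  dense <- mk_matrix(matrix(runif(40), 4))
  expect_identical(filter_matrix(dense, 1L, 0.5), dense)
})

test_that("mean imputation fills with the cell mean and preserves it", {
  v <- matrix(c(0.2, 0.6, NA,
                0.1, 0.3, 0.5), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  m <- mk_matrix(v)
  d <- impute_mean(m)
  expect_equal(unname(d["a", 3]), 0.4)
  expect_equal(d["b", ], v["b", ], ignore_attr = TRUE)  # dense row untouched
  expect_equal(rowMeans(d), rowMeans(v, na.rm = TRUE))
  all_na <- mk_matrix(matrix(c(NA_real_, NA_real_), 1))
  expect_error(impute_mean(all_na), "imputed")
})

test_that("three simulated groups separate with high ARI, deterministically", {
  cfg <- sim_config(seed = 6, n_chromosomes = 2, chrom_length = 100000L)
  ref <- simulate_reference(cfg)
  groups <- stats::setNames(rep(1:3, each = 20), sprintf("cell%03d", 1:60))
  calls <- simulate_group_calls(ref, groups, sites_per_cell = 1500L, seed = 6)
  m <- build_bin_matrix(calls, nchar(ref$reference), bin_size = 10000L)
  f <- filter_matrix(m, min_bins_per_cell = 10L,
                     min_cell_fraction_per_bin = 0.5)
  dense <- impute_mean(f)
  emb <- embed_and_cluster(dense, n_pcs = 20L, seed = 6)
  expect_gte(length(unique(emb$cluster_labels)), 3L)
  expect_gte(ari(emb$cluster_labels, groups[names(emb$cluster_labels)]), 0.9)
  # determinism and duplicate-cell coincidence
  emb2 <- embed_and_cluster(dense, n_pcs = 20L, seed = 6)
  expect_identical(emb$cluster_labels, emb2$cluster_labels)
  expect_identical(emb$umap_xy, emb2$umap_xy)
  dup <- rbind(dense, dense[1, , drop = FALSE])
  rownames(dup)[nrow(dup)] <- "dup"
  emb3 <- embed_and_cluster(dup, n_pcs = 10L, seed = 1)
  expect_equal(unname(emb3$pcs["dup", ]), unname(emb3$pcs[1, ]))
  expect_error(embed_and_cluster(dense[1:2, ]), "3 cells")
})

test_that("promoter methylation pools counts and ranks planted differences first", {
  promoters <- data.frame(gene = c("g1", "g2", "g3"), chrom = "chr1",
                          start = c(0L, 2000L, 4000L),
                          end = c(2000L, 4000L, 6000L), strand = "+")
  base <- expand.grid(cell = c("a1", "a2", "b1", "b2"),
                      pos = c(500L, 2500L, 4500L), stringsAsFactors = FALSE)
  base$chrom <- "chr1"; base$strand <- "+"; base$context <- "WCG"
  base$meth <- 2L; base$total <- 4L
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  same <- promoter_methylation(base, promoters, groups, reference_group = "A")
  expect_true(all(same$differences$delta == 0))
  # plant a Delta = +0.4 on g2 in group B
  shifted <- base
  shifted$meth[shifted$pos == 2500L & shifted$cell %in% c("b1", "b2")] <- 3.6
  res <- promoter_methylation(shifted, promoters, groups, reference_group = "A")
  expect_equal(res$differences$gene[1], "g2")
  expect_equal(res$differences$delta[1], 0.4, tolerance = 1e-9)
  # pooled definition: sum(meth)/sum(total), not mean of per-cell ratios
  uneven <- data.frame(cell = c("a1", "a2"), chrom = "chr1",
                       pos = c(500L, 600L), strand = "+", context = "WCG",
                       meth = c(1L, 9L), total = c(1L, 18L))
  g2 <- c(a1 = "A", a2 = "A")
  pooled <- promoter_methylation(uneven, promoters[1, ], g2)
  expect_equal(unname(pooled$levels["g1", "A"]), 10 / 19)
  cellwise <- promoter_methylation(uneven, promoters[1, ], g2,
                                   method = "mean_of_cells")
  expect_equal(unname(cellwise$levels["g1", "A"]), mean(c(1, 0.5)))
})
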