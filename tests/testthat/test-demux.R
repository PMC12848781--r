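test_that("levenshtein matches a dynamic-programming oracle", {
  expect_equal(levenshtein("ACGT", "ACGT"), 0L)
  expect_equal(levenshtein("ACGT", "ACGA"), 1L)
  expect_equal(levenshtein("AAAA", "TTT"), 4L)
  set.seed(21)
  for (i in 1:50) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:10, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:10, 1), TRUE), collapse = "")
    expect_equal(levenshtein(a, b), dp_levenshtein(a, b))
    expect_equal(levenshtein(a, b), levenshtein(b, a))  # symmetry
  }
})

test_that("barcode correction recovers <=2-distance barcodes and discards the rest", {
  expect_equal(correct_barcode("AAAA", c("AAAA", "TTTT")), "AAAA")
  expect_equal(correct_barcode("AAAT", c("AAAA", "TTTT")), "AAAA")
  # distance 3 from everything -> unknown
  expect_true(is.na(correct_barcode("AATT", c("AAAAAA", "TTTTTT"))))
  # tie at the minimum -> unknown
  expect_true(is.na(correct_barcode("AATT", c("AATA", "AATG"))))
  # exhaustive agreement with the whole-whitelist distance computation
  wl <- generate_whitelist(16, length = 6, seed = 2)
  set.seed(3)
  for (i in 1:500) {
    obs <- paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
    d <- vapply(wl, function(w) dp_levenshtein(obs, w), numeric(1))
    expected <- if (min(d) <= 2 && sum(d == min(d)) == 1) wl[which.min(d)]
                else NA_character_
    expect_identical(correct_barcode(obs, wl), unname(expected))
  }
})

test_that("read parsing enforces linker structure at fixed offsets", {
  wl <- generate_whitelist(4, length = 6, seed = 5)
  layout <- read_layout("ACGTAC", "TTGGCC", 6, wl[1:2], wl[3:4],
                        linker_max_mismatch = 1L)
  genomic <- strrep("A", 30)
  good <- paste0("ACGTAC", wl[3], "TTGGCC", wl[1], genomic)
  p <- parse_read(good, layout)
  expect_true(p$ok)
  expect_equal(p$barcode_A_raw, wl[1])
  expect_equal(p$barcode_B_raw, wl[3])
  expect_equal(p$genomic, genomic)
  # linker replaced by random sequence -> unknown structure
  bad <- paste0("GGGGGG", wl[3], "TTGGCC", wl[1], genomic)
  expect_false(parse_read(bad, layout)$ok)
  # exactly max mismatches accepted, one more rejected
  mm1 <- paste0("TCGTAC", wl[3], "TTGGCC", wl[1], genomic)
  mm2 <- paste0("TGGTAC", wl[3], "TTGGCC", wl[1], genomic)
  expect_true(parse_read(mm1, layout)$ok)
  expect_false(parse_read(mm2, layout)$ok)
  # too-short read -> unknown structure
  expect_false(parse_read("ACGTAC", layout)$ok)
})

test_that("noiseless demultiplexing recovers every read's truth cell", {
  s <- small_sim(seed = 13, n_cells = 8, reads_per_cell = 25,
                 barcode_error_rate = 0)
  dmx <- demultiplex(data.frame(read_id = s$sim$reads$read_id,
                                seq1 = s$sim$reads$seq1), s$sim$layout)
  expect_equal(dmx$report$n_assigned, nrow(s$sim$reads))
  expect_equal(dmx$report$n_unknown_structure, 0L)
  expect_equal(dmx$report$n_unknown_barcode, 0L)
  map <- truth_cell_of(s$sim)
  expect_true(all(map[dmx$assigned$cell] ==
                    s$sim$truth$cell_assignments[dmx$assigned$read_id]))
})

test_that("demux counters reconcile under barcode errors and flag far barcodes", {
  s <- small_sim(seed = 17, n_cells = 10, reads_per_cell = 40,
                 barcode_error_rate = 0.04)
  reads <- data.frame(read_id = s$sim$reads$read_id, seq1 = s$sim$reads$seq1)
  dmx <- demultiplex(reads, s$sim$layout)
  r <- dmx$report
  expect_equal(r$n_total, r$n_unknown_structure + r$n_unknown_barcode +
                 r$n_assigned)
  expect_equal(sum(unlist(r$per_cell_counts)), r$n_assigned)
  # every assigned read maps to its truth cell (distance-<=2 errors are
  # correctable because whitelists are distance->=3 apart)
  map <- truth_cell_of(s$sim)
  truth <- s$sim$truth$cell_assignments[dmx$assigned$read_id]
  got <- unname(map[dmx$assigned$cell])  # NA if corrected to an unused combo
  expect_gt(mean(!is.na(got) & got == truth), 0.99)
})

test_that("empty input gives an all-zero report", {
  wl <- generate_whitelist(4, length = 6, seed = 5)
  layout <- read_layout("ACGTAC", "TTGGCC", 6, wl[1:2], wl[3:4])
  dmx <- demultiplex(data.frame(read_id = character(0), seq1 = character(0)),
                     layout)
  expect_equal(dmx$report$n_total, 0L)
  expect_equal(dmx$report$n_assigned, 0L)
  expect_equal(nrow(dmx$assigned), 0L)
})

test_that("deduplication is coordinate- and cell-aware", {
  rec <- data.frame(
    cell = c("a", "a", "b", "a"),
    chrom = c("chr1", "chr1", "chr1", "chr1"),
    start = c(100L, 100L, 100L, 200L),
    strand = c("+", "+", "+", "+"),
    tag = 1:4
  )
  dd <- dedup_records(rec)
  expect_equal(dd$n_removed, 1L)
  # first-in-input-order survivor kept; other cells untouched
  expect_equal(dd$records$tag, c(1L, 3L, 4L))
  all_unique <- dedup_records(rec[c(1, 3, 4), ])
  expect_equal(all_unique$n_removed, 0L)
})

test_that("species mixing labels follow the purity threshold with >= boundary", {
  res <- species_mix_classify(c(980, 550, 900, 20), c(20, 450, 100, 980),
                              purity_threshold = 0.9, min_reads = 100)
  expect_equal(res$label, c("speciesA", "collision", "speciesA", "speciesB"))
  below <- species_mix_classify(50, 40, min_reads = 1000)
  expect_equal(below$label, "excluded")
  exact <- species_mix_classify(90, 10, purity_threshold = 0.9, min_reads = 10)
  expect_equal(exact$label, "speciesA")
})

test_that("closed-form collision rate matches hand values and is monotone", {
  expect_equal(expected_collision_rate(1, 4608), 0)
  expect_equal(expected_collision_rate(2, 1), 1)
  expect_equal(expected_collision_rate(200, 48 * 96), 0.0423, tolerance = 1e-2)
  n <- c(10, 50, 100, 200, 400)
  r <- vapply(n, expected_collision_rate, numeric(1), n_combinations = 4608)
  expect_true(all(diff(r) > 0))
  b <- c(1000, 2000, 4608, 10000)
  r2 <- vapply(b, function(bb) expected_collision_rate(200, bb), numeric(1))
  expect_true(all(diff(r2) < 0))
})

test_that("Monte-Carlo collision rate agrees with the closed form within 3 SE", {
  mc <- simulate_collision_rate(200, 4608, n_reps = 2000, seed = 8)
  expect_lt(abs(mc$rate - expected_collision_rate(200, 4608)), 3 * mc$se)
})
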