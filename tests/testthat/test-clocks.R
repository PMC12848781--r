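test_that("training recovers exact slopes on noiseless data and ranks by |r|", {
  ref <- simulate_age_reference(n_samples = 40, n_sites = 100, noise_sd = 0,
                                frac_age_linear = 1, seed = 73)
  model <- train_age_model(ref$beta, ref$ages, top_fraction = 1)
  clipped <- apply(ref$beta, 2, function(b) any(b %in% c(0, 1)))
  expect_equal(unname(model$slope[!clipped]),
               unname(ref$true_slopes[!clipped]), tolerance = 1e-10)
  expect_equal(length(model$selected), length(model$sites))
  # constant sites are dropped and counted
  beta2 <- ref$beta
  beta2[, 1] <- 0.5
  m2 <- train_age_model(beta2, ref$ages, top_fraction = 1)
  expect_equal(m2$n_dropped_constant, 1L)
  expect_false("cg000001" %in% m2$sites)
  expect_error(train_age_model(ref$beta[1:10, ], ref$ages[1:10]), "20")
})

test_that("binarization uses the >= 0.5 convention", {
  calls <- data.frame(site = c("s1", "s2", "s3"),
                      meth = c(3L, 0L, 1L), total = c(4L, 5L, 2L))
  x <- binarize_calls(calls)
  expect_equal(unname(x), c(1L, 0L, 1L))
  expect_equal(binarize_calls(stats::setNames(c(0.49, 0.5), c("a", "b"))),
               stats::setNames(c(0L, 1L), c("a", "b")))
})

test_that("profile likelihood behaves monotonically and symmetrically", {
  model <- structure(list(
    sites = "s1",
    slope = c(s1 = 0.005), intercept = c(s1 = 0.2),
    pearson_r = c(s1 = 0.9), selected = "s1",
    age_range = c(30, 80), n_dropped_constant = 0L
  ), class = "age_model")
  grid <- seq(10, 100, by = 0.1)
  # single positive-slope site with x = 1: likelihood increases with age
  up <- predict_age(c(s1 = 1L), model, grid = grid, min_sites = 1L)
  expect_equal(up$predicted_age, 100)
  # flipping the state with the mirrored model (beta -> 1 - beta, i.e.
  # slope negated, intercept reflected) leaves the profile unchanged
  model_neg <- model
  model_neg$slope <- c(s1 = -0.005)
  model_neg$intercept <- c(s1 = 0.8)
  down <- predict_age(c(s1 = 0L), model_neg, grid = grid, min_sites = 1L)
  expect_equal(down$profile, up$profile, tolerance = 1e-12)
  # coverage guard: too few overlapping sites refuses prediction
  refuse <- predict_age(c(s1 = 1L), model, grid = grid, min_sites = 2L)
  expect_true(is.na(refuse$predicted_age))
  expect_equal(refuse$n_sites_used, 1L)
})

test_that("cells simulated from the model are dated accurately", {
  ref <- simulate_age_reference(n_samples = 100, n_sites = 5000,
                                noise_sd = 0.05, seed = 79)
  model <- train_age_model(ref$beta, ref$ages)
  ages <- seq(32, 78, length.out = 40)
  sim <- simulate_clock_cells(model, ages, n_sites_covered = 500L, seed = 79)
  pred <- predict_ages(sim$states, model)
  expect_true(all(!is.na(pred$predicted_age)))
  rmse <- sqrt(mean((pred$predicted_age - sim$ages)^2))
  expect_lt(rmse, 10)
  expect_gt(stats::cor(pred$predicted_age, sim$ages), 0.8)
  # predictions are invariant to site ordering
  shuffled <- lapply(sim$states, function(x) x[sample(names(x))])
  names(shuffled) <- names(sim$states)
  pred2 <- predict_ages(shuffled, model)
  expect_equal(pred$predicted_age, pred2$predicted_age)
})

test_that("a hypermethylation shift at age-positive sites raises predicted age", {
  ref <- simulate_age_reference(n_samples = 100, n_sites = 4000,
                                noise_sd = 0.05, seed = 83)
  model <- train_age_model(ref$beta, ref$ages)
  ages <- rep(50, 30)
  normal <- simulate_clock_cells(model, ages, n_sites_covered = 400L,
                                 seed = 83)
  # tumour-like: constant positive methylation offset applied at sites
  # with positive slope via the generator's offset hook restricted by sign
  pos_model <- model
  pos_model$selected <- model$selected[model$slope[model$selected] > 0]
  shifted <- simulate_clock_cells(pos_model, ages, n_sites_covered = 400L,
                                  offset = 0.15, seed = 83)
  p_norm <- predict_ages(normal$states, model)
  p_shift <- predict_ages(shifted$states, model)
  expect_gt(mean(p_shift$predicted_age), mean(p_norm$predicted_age))
})

test_that("cross-validation is seeded and approaches r = 1 without noise", {
  ref <- simulate_age_reference(n_samples = 60, n_sites = 3000,
                                noise_sd = 0.05, seed = 89)
  cv1 <- crossvalidate_age_model(ref$beta, ref$ages, seed = 4)
  cv2 <- crossvalidate_age_model(ref$beta, ref$ages, seed = 4)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_gt(cv1$pearson_r, 0.8)
  noiseless <- simulate_age_reference(n_samples = 100, n_sites = 5000,
                                      noise_sd = 0, frac_age_linear = 1,
                                      seed = 97)
  cv0 <- crossvalidate_age_model(noiseless$beta, noiseless$ages,
                                 downsample_sites = 5000L, seed = 4)
  expect_gt(cv0$pearson_r, 0.98)
})

test_that("mitotic score averages clock-site levels and is monotone", {
  calls <- data.frame(cell = "c", chrom = "chr1", pos = c(10L, 20L, 30L),
                      strand = "+", context = "WCG",
                      meth = c(1L, 2L, 9L), total = c(5L, 5L, 9L))
  sites <- c("chr1:10:+", "chr1:20:+")
  ms <- mitotic_score(calls, sites)
  expect_equal(ms$cdr, mean(c(0.2, 0.4)))
  expect_equal(ms$n_sites_covered, 2L)
  full <- calls; full$meth <- full$total
  expect_equal(mitotic_score(full, sites)$cdr, 1)
  bumped <- calls; bumped$meth[1] <- 2L
  expect_gte(mitotic_score(bumped, sites)$cdr, ms$cdr)
  none <- mitotic_score(calls, "chrX:1:+")
  expect_true(is.na(none$cdr))
})

test_that("hypergeometric overlap test matches enumeration", {
  expect_equal(clock_overlap_test(character(0), c("a", "b"), 100)$p, 1)
  set_a <- sprintf("s%02d", 1:10)
  set_b <- c(sprintf("s%02d", 6:10), sprintf("t%02d", 1:5))  # overlap 5
  got <- clock_overlap_test(set_a, set_b, 100)
  expect_equal(got$overlap, 5L)
  expect_equal(got$p, oracle_hyper_upper(5, 10, 10, 100), tolerance = 1e-12)
  # complete containment gives the extreme tail
  contained <- clock_overlap_test(set_a[1:3], set_a, 50)
  expect_equal(contained$p, oracle_hyper_upper(3, 3, 10, 50),
               tolerance = 1e-12)
  expect_error(clock_overlap_test(sprintf("x%d", 1:20), "a", 10), "universe")
})
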