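#' Train a per-site linear epigenetic-age model
#'
#' Fits, for every CpG site in a bulk reference matrix, an ordinary
#' least-squares regression of methylation beta on chronological age,
#' records the Pearson correlation, ranks sites by |r|, and keeps the
#' top fraction (default 10%) as the predictive set. Sites with
#' constant beta have undefined correlation and are dropped (counted).
#'
#' @param beta samples x sites matrix of methylation beta values
#'   (column names are site identifiers).
#' @param ages numeric vector of sample ages in years.
#' @param top_fraction fraction of usable sites to keep, ranked by |r|
#'   (default 0.10).
#' @return object of class `age_model`: list with `sites`, `slope`,
#'   `intercept`, `pearson_r` (aligned named vectors over all usable
#'   sites), `selected` (character vector of predictive sites),
#'   `age_range`, `n_dropped_constant`.
#' @export
train_age_model <- function(beta, ages, top_fraction = 0.10) {
  stopifnot(nrow(beta) == length(ages))
  if (nrow(beta) < 20L) stop("need at least 20 training samples")
  if (diff(range(ages)) <= 0) stop("training ages must span a positive range")
  age_c <- ages - mean(ages)
  ss_age <- sum(age_c^2)
  # vectorised per-site OLS: slope_s = cov(age, beta_s) / var(age)
  col_means <- colMeans(beta)
  cov_ab <- as.numeric(crossprod(age_c, beta)) / (length(ages) - 1L)
  var_a <- ss_age / (length(ages) - 1L)
  sd_b <- apply(beta, 2L, stats::sd)
  usable <- sd_b > 0
  slope <- cov_ab / var_a
  intercept <- col_means - slope * mean(ages)
  r <- ifelse(usable, cov_ab / (sqrt(var_a) * sd_b), NA_real_)
  sites <- colnames(beta)[usable]
  model <- list(
    sites = sites,
    slope = stats::setNames(slope[usable], sites),
    intercept = stats::setNames(intercept[usable], sites),
    pearson_r = stats::setNames(r[usable], sites),
    selected = sites[order(-abs(r[usable]))][
      seq_len(max(1L, round(top_fraction * length(sites))))],
    age_range = range(ages),
    n_dropped_constant = sum(!usable)
  )
  class(model) <- "age_model"
  model
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("age_model: %d sites (%d selected, %d constant sites dropped)\n",
              length(x$sites), length(x$selected), x$n_dropped_constant))
  cat(sprintf("training ages %.1f-%.1f years; |r| of selected sites %.2f-%.2f\n",
              x$age_range[1], x$age_range[2],
              min(abs(x$pearson_r[x$selected])),
              max(abs(x$pearson_r[x$selected]))))
  invisible(x)
}

#' Binarize single-cell methylation calls at model sites
#'
#' A covered site is 1 if its methylation level is at least 0.5 (exact
#' halves round up — documented convention), else 0.
#'
#' @param calls methylation-call table for one cell, with a `site`
#'   column of CpG identifiers (or `chrom`/`pos`/`strand` to be pasted
#'   into identifiers), or a named numeric vector of levels.
#' @param sites optional restriction to these site identifiers.
#' @param threshold binarization threshold (default 0.5, `>=` rule).
#' @return named integer vector of 0/1 states over covered sites.
#' @export
binarize_calls <- function(calls, sites = NULL, threshold = 0.5) {
  if (is.numeric(calls)) {
    lev <- calls
  } else {
    id <- if ("site" %in% names(calls)) calls$site else
      paste0(calls$chrom, ":", calls$pos, ":", calls$strand)
    lev <- stats::setNames(calls$meth / calls$total, id)
  }
  if (!is.null(sites)) lev <- lev[names(lev) %in% sites]
  stats::setNames(as.integer(lev >= threshold), names(lev))
}

#' Predict a cell's epigenetic age by profile likelihood
#'
#' For each candidate age on a grid, each selected model site
#' contributes a Bernoulli log-likelihood with success probability
#' `clamp(intercept + slope * age, clip, 1 - clip)`; the cell's
#' predicted age is the grid argmax over its covered selected sites
#' (ties break to the lowest age and raise `flat_flag`, as does a
#' profile whose spread is numerically negligible). The grid extends
#' the training age range by 20 years on both sides at 0.1-year steps,
#' so accelerated ageing beyond the training maximum remains
#' representable.
#'
#' @param states named 0/1 vector from [binarize_calls()].
#' @param model an `age_model`.
#' @param grid numeric vector of candidate ages (default: training
#'   range +/- 20 years, step 0.1).
#' @param clip clamp for predicted betas (default 0.001).
#' @param min_sites minimum covered selected sites (default 100);
#'   cells below it are refused (`NA` age).
#' @return list `predicted_age`, `n_sites_used`, `loglik_max`,
#'   `flat_flag`, `profile` (loglik over the grid).
#' @export
predict_age <- function(states, model, grid = NULL, clip = 0.001,
                        min_sites = 100L) {
  stopifnot(inherits(model, "age_model"))
  if (is.null(grid)) {
    grid <- seq(model$age_range[1] - 20, model$age_range[2] + 20, by = 0.1)
  }
  use <- intersect(names(states), model$selected)
  if (length(use) < min_sites) {
    return(list(predicted_age = NA_real_, n_sites_used = length(use),
                loglik_max = NA_real_, flat_flag = NA, profile = NULL))
  }
  x <- states[use]
  b <- outer(model$slope[use], grid) + model$intercept[use]  # sites x ages
  b <- pmin(pmax(b, clip), 1 - clip)
  loglik <- as.numeric(crossprod(log(b), x) + crossprod(log1p(-b), 1 - x))
  best <- which.max(loglik)  # first maximum = lowest age on ties
  flat <- (max(loglik) - min(loglik)) < 1e-8 ||
    sum(loglik == max(loglik)) > 1L
  list(predicted_age = grid[best], n_sites_used = length(use),
       loglik_max = loglik[best], flat_flag = flat,
       profile = stats::setNames(loglik, grid))
}

#' Predict ages for many cells
#'
#' @param states_list list of named 0/1 vectors, one per cell.
#' @inheritParams predict_age
#' @return data.frame `cell`, `predicted_age`, `n_sites_used`,
#'   `loglik_max`, `flat_flag`.
#' @export
predict_ages <- function(states_list, model, grid = NULL, clip = 0.001,
                         min_sites = 100L) {
  out <- lapply(names(states_list), function(cl) {
    p <- predict_age(states_list[[cl]], model, grid = grid, clip = clip,
                     min_sites = min_sites)
    data.frame(cell = cl, predicted_age = p$predicted_age,
               n_sites_used = p$n_sites_used, loglik_max = p$loglik_max,
               flat_flag = p$flat_flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cross-validate the age model under single-cell-like sparsity
#'
#' Five-fold cross-validation stratified by age quantile: the model is
#' trained on four folds; each held-out sample is binarized and
#' randomly downsampled to `downsample_sites` covered sites (mimicking
#' the sparse site recovery of single cells) before profile-likelihood
#' prediction. Reports the Pearson correlation of predicted versus
#' chronological age.
#'
#' @param beta,ages training reference as in [train_age_model()].
#' @param k folds (default 5).
#' @param downsample_sites covered sites kept per held-out sample
#'   (default 2300).
#' @param top_fraction passed to [train_age_model()].
#' @param min_sites passed to [predict_age()].
#' @param seed integer seed (folds and downsampling).
#' @return list `predictions` (data.frame `sample`, `age`,
#'   `predicted_age`, `fold`), `pearson_r`.
#' @export
crossvalidate_age_model <- function(beta, ages, k = 5L,
                                    downsample_sites = 2300L,
                                    top_fraction = 0.10, min_sites = 100L,
                                    seed = 1L) {
  n <- nrow(beta)
  withr_seed(seed, {
    strata <- cut(rank(ages, ties.method = "first"),
                  breaks = k, labels = FALSE)
    fold <- integer(n)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    preds <- vector("list", k)
    for (f in seq_len(k)) {
      test <- which(fold == f)
      model <- train_age_model(beta[-test, , drop = FALSE], ages[-test],
                               top_fraction = top_fraction)
      pa <- vapply(test, function(i) {
        states <- as.integer(beta[i, ] >= 0.5)
        names(states) <- colnames(beta)
        keep <- sample(names(states),
                       min(downsample_sites, length(states)))
        p <- predict_age(states[keep], model, min_sites = min_sites)
        p$predicted_age
      }, numeric(1))
      preds[[f]] <- data.frame(sample = rownames(beta)[test],
                               age = ages[test], predicted_age = pa,
                               fold = f, stringsAsFactors = FALSE)
    }
  })
  predictions <- do.call(rbind, preds)
  ok <- !is.na(predictions$predicted_age)
  list(predictions = predictions,
       pearson_r = stats::cor(predictions$age[ok],
                              predictions$predicted_age[ok]))
}

#' Mitotic-clock score (cell division rate proxy)
#'
#' Mean methylation level over a supplied clock CpG set, from pooled
#' counts per site: a cumulative-division proxy in the spirit of
#' methylation-based mitotic clocks. Raising any site's level never
#' decreases the score.
#'
#' @param calls methylation-call table (one cell or a pseudo-bulk), or
#'   a pooled table from [pseudo_bulk()].
#' @param clock_sites character vector of site identifiers
#'   (`"chrom:pos:strand"`).
#' @return list `cdr` (mean level over covered clock sites; `NA` if no
#'   clock site is covered), `n_sites_covered`.
#' @export
mitotic_score <- function(calls, clock_sites) {
  id <- paste0(calls$chrom, ":", calls$pos, ":", calls$strand)
  sel <- id %in% clock_sites
  if (!any(sel)) return(list(cdr = NA_real_, n_sites_covered = 0L))
  key <- id[sel]
  meth <- rowsum(calls$meth[sel], key)
  total <- rowsum(calls$total[sel], key)
  list(cdr = mean(meth[, 1] / total[, 1]), n_sites_covered = nrow(meth))
}

#' Hypergeometric overlap test between two CpG site sets
#'
#' Upper-tail probability of observing at least the given overlap when
#' `|A|` sites are drawn from a universe containing `|B|` marked sites.
#'
#' @param set_a,set_b character vectors of site identifiers.
#' @param universe_size total number of sites both sets are drawn from.
#' @return list `overlap`, `p` (P(overlap >= observed)).
#' @export
clock_overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) > universe_size || length(set_b) > universe_size) {
    stop("set larger than universe")
  }
  ov <- length(intersect(set_a, set_b))
  p <- if (ov == 0L) 1 else
    stats::phyper(ov - 1L, length(set_b), universe_size - length(set_b),
                  length(set_a), lower.tail = FALSE)
  list(overlap = ov, p = p)
}
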