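#' Summary statistics of a Het_FE clone-VAF distribution (25 values)
#'
#' Twenty bin counts of clone-VAF over (0.5-5\%, 5-10\%, ..., 95-100\%),
#' the mean and SD of clone-VAF, and the proportions of clones that are
#' wild type (< 5\%), heteroplasmic (5-90\%) and homoplasmic (> 90\%).
#' VAFs below the 0.5\% detection floor contribute only to the wild-type
#' proportion, the mean and the SD, never to a bin.
#'
#' @param vafs clone-VAFs (zeros included).
#' @return named numeric vector of length 25.
#' @export
hetfe_summary_stats <- function(vafs) {
  if (!length(vafs)) stop("empty clone-VAF vector")
  breaks <- c(0.005, seq(0.05, 1, by = 0.05))
  bins <- table(cut(vafs[vafs >= 0.005], breaks = breaks,
                    include.lowest = TRUE, right = TRUE))
  stats_ <- c(as.vector(bins),
              mean(vafs), sd(vafs),
              mean(vafs < 0.05), mean(vafs >= 0.05 & vafs <= 0.9),
              mean(vafs > 0.9))
  names(stats_) <- c(paste0("bin_", sprintf("%02d", seq_len(20))),
                     "mean_vaf", "sd_vaf", "prop_wt", "prop_het", "prop_hom")
  stats_
}

#' Summary statistics of per-clone PZ_simple mutation ledgers (22 values)
#'
#' Twenty bin counts of the per-cell maximum clone-VAF over the same bins
#' as [hetfe_summary_stats()] (detection floor 0.5\%), plus the counts of
#' cells carrying two and three homoplasmic (clone-VAF > 90\%) mutations.
#'
#' @param ledgers list of numeric vectors, one per cell/clone, each the
#'   clone-VAFs of its PZ_simple mutations (possibly empty).
#' @return named numeric vector of length 22.
#' @export
pz_summary_stats <- function(ledgers) {
  breaks <- c(0.005, seq(0.05, 1, by = 0.05))
  maxv <- vapply(ledgers, function(v) if (length(v)) max(v) else 0, numeric(1))
  bins <- table(cut(maxv[maxv >= 0.005], breaks = breaks,
                    include.lowest = TRUE, right = TRUE))
  n_hom <- vapply(ledgers, function(v) sum(v > 0.9), numeric(1))
  stats_ <- c(as.vector(bins), sum(n_hom == 2), sum(n_hom == 3))
  names(stats_) <- c(paste0("bin_", sprintf("%02d", seq_len(20))),
                     "cells_two_hom", "cells_three_hom")
  stats_
}

# mean squared error between observed and simulated statistics; counts are
# converted to proportions of n_sampled, and (optionally) every statistic is
# standardized by its SD across candidate draws
mse_table <- function(obs, sims, n_sampled, count_idx, standardize = TRUE) {
  obs2 <- obs
  sims2 <- sims
  obs2[count_idx] <- obs2[count_idx] / n_sampled
  sims2[, count_idx] <- sims2[, count_idx] / n_sampled
  if (standardize) {
    sdv <- apply(sims2, 2L, sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    sims2 <- sweep(sims2, 2L, sdv, "/")
    obs2 <- obs2 / sdv
  }
  rowMeans(sweep(sims2, 2L, obs2, "-")^2)
}

#' Infer mtDNA turnover rates from Het_FE clone-VAF distributions
#'
#' MSE-rejection inference: for each Het_FE variant with caVAF > 0.005,
#' forward simulations are run at the donor's mean mtDNA copy number with
#' initial frequency equal to the caVAF; per candidate turnover count `g`
#' the donor's clone count is resampled `n_resample` times from the
#' simulated cells, 25 summary statistics are computed each time and
#' compared with the observed statistics.  The per-variant estimate is the
#' mean `g` over the `n_keep` lowest-MSE draws divided by donor age; tissue
#' aggregates are means with normal-approximation 95\% CIs across variants.
#'
#' @param cohort an `mt_cohort`.
#' @param classified output of [classify_variants()].
#' @param model turnover model.
#' @param g_grid candidate total-turnover counts (default 0 to `g_max` in
#'   steps of `g_step`).
#' @param g_max,g_step grid construction when `g_grid` is NULL.
#' @param n_cells simulated cells per variant.
#' @param n_resample sequencing resamples per candidate, default 100.
#' @param n_keep lowest-MSE draws retained, default 50.
#' @param min_cavaf caVAF floor for inclusion, default 0.005.
#' @param standardize standardize statistics by their across-draw SD before
#'   the MSE.  Default FALSE: once counts are converted to proportions all
#'   statistics share a scale, and SD-standardization overweights rarely
#'   populated bins, degrading parameter recovery.
#' @param copy_number optional named vector of donor mean copy numbers;
#'   defaults to `mtdna_copy_number()` of the donor's clone coverages.
#' @param seed optional seed.
#' @return object of class `mt_turnover_fit` with `variants` (per-variant
#'   estimates and ranges), `tissue` (aggregates) and the call settings.
#' @export
infer_turnover_rate <- function(cohort, classified,
                                model = c("mitotic", "homeostatic"),
                                g_grid = NULL, g_max = 5000L, g_step = 25L,
                                n_cells = 2000L, n_resample = 100L,
                                n_keep = 50L, min_cavaf = 0.005,
                                standardize = FALSE, copy_number = NULL,
                                seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  cv <- compute_cavaf(cohort, classified, class = "Het_FE")
  cv <- cv[cv$cavaf > min_cavaf, , drop = FALSE]
  if (!nrow(cv)) stop("no Het_FE variant with caVAF > ", min_cavaf)
  meta <- cohort$clones
  donor_meta <- unique(meta[, c("donor_id", "tissue", "donor_age")])
  if (is.null(copy_number)) {
    cn <- tapply(mtdna_copy_number(meta$mean_coverage_mt,
                                   meta$mean_coverage_nuclear),
                 meta$donor_id, mean)
  } else cn <- copy_number
  if (is.null(g_grid)) g_grid <- seq(0L, g_max, by = g_step)

  rows <- lapply(seq_len(nrow(cv)), function(i) {
    d <- cv$donor_id[i]
    n <- max(2L, as.integer(round(cn[[d]])))
    p0 <- cv$cavaf[i]
    clones <- meta$clone_id[meta$donor_id == d]
    # observed clone-VAF distribution from the raw measurements: carrier
    # clones below the reconciliation threshold keep their measured VAF
    # (background noise at a true site is negligible next to the signal),
    # so the observed statistics match what the simulator generates
    mm <- cohort$measurements
    hit <- mm$position == cv$position[i] & mm$ref == cv$ref[i] &
      mm$alt == cv$alt[i] & mm$clone_id %in% clones
    v <- setNames(rep(0, length(clones)), clones)
    v[mm$clone_id[hit]] <- mm$vaf[hit]
    obs <- hetfe_summary_stats(unname(v))

    sim <- simulate_drift(drift_config(n = n, p0 = p0,
                                       g_max = max(g_grid),
                                       n_cells = n_cells, model = model),
                          record_at = g_grid)
    n_obs <- length(v)
    draws_g <- rep(g_grid, each = n_resample)
    sims <- matrix(0, nrow = length(draws_g), ncol = 25L)
    row <- 1L
    for (gi in seq_along(g_grid)) {
      fr <- sim$freq[gi, ]
      for (r_ in seq_len(n_resample)) {
        sims[row, ] <- hetfe_summary_stats(fr[sample.int(n_cells, n_obs)])
        row <- row + 1L
      }
    }
    mse <- mse_table(obs, sims, n_obs, seq_len(20), standardize)
    keep <- order(mse)[seq_len(min(n_keep, length(mse)))]
    gk <- draws_g[keep]
    age <- donor_meta$donor_age[donor_meta$donor_id == d][1]
    data.frame(position = cv$position[i], ref = cv$ref[i], alt = cv$alt[i],
               donor_id = d, tissue = donor_meta$tissue[donor_meta$donor_id == d][1],
               cavaf = p0, n_copy = n, donor_age = age,
               g_hat = mean(gk), g_min = min(gk), g_max = max(gk),
               rate = if (age > 0) mean(gk) / age else NA_real_,
               rate_min = if (age > 0) min(gk) / age else NA_real_,
               rate_max = if (age > 0) max(gk) / age else NA_real_,
               stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, rows)
  tissue <- do.call(rbind, lapply(split(variants, variants$tissue), function(s) {
    rr <- s$rate[!is.na(s$rate)]
    se <- if (length(rr) > 1) sd(rr) / sqrt(length(rr)) else NA_real_
    data.frame(tissue = s$tissue[1], rate = mean(rr),
               ci_lo = mean(rr) - 1.96 * se, ci_hi = mean(rr) + 1.96 * se,
               n_variants = length(rr), stringsAsFactors = FALSE)
  }))
  structure(list(variants = variants, tissue = tissue, model = model,
                 g_grid = g_grid, n_cells = n_cells,
                 n_resample = n_resample, n_keep = n_keep),
            class = "mt_turnover_fit")
}

#' @export
print.mt_turnover_fit <- function(x, ...) {
  cat("mt_turnover_fit (", x$model, " model): ", nrow(x$variants),
      " Het_FE variant(s)\n", sep = "")
  for (i in seq_len(nrow(x$tissue)))
    cat(sprintf("  %s: %.1f turnovers/year (95%% CI %.1f-%.1f, %d variants)\n",
                x$tissue$tissue[i], x$tissue$rate[i], x$tissue$ci_lo[i],
                x$tissue$ci_hi[i], x$tissue$n_variants[i]))
  invisible(x)
}

#' @export
summary.mt_turnover_fit <- function(object, ...) {
  print(object)
  cat("per-variant estimates:\n")
  print(object$variants[, c("donor_id", "cavaf", "g_hat", "rate",
                            "rate_min", "rate_max")])
  invisible(object)
}

#' @export
coef.mt_turnover_fit <- function(object, ...) {
  setNames(object$tissue$rate, object$tissue$tissue)
}

#' Infer the mtDNA mutation rate from PZ_simple summary statistics
#'
#' For each donor, `log10(r)` is drawn uniformly from `log10r_range`; each
#' draw runs a mutation-accumulation simulation at the donor's copy number
#' for `g = turnover_rate * age` turnovers, resamples the donor's clone
#' count `n_resample` times, computes 22 summary statistics and their MSE
#' against the observed statistics.  The estimate is the mean `log10(r)`
#' over the `n_keep` lowest-MSE draws (reported as `10^mean`), with the
#' min-max range.
#'
#' @param cohort an `mt_cohort`.
#' @param classified output of [classify_variants()].
#' @param turnover_rates named vector: turnover rate per year by tissue
#'   (e.g. `coef()` of an [infer_turnover_rate()] fit).
#' @param model turnover model (must match the rates).
#' @param n_draws rate draws per donor, default 1,000.
#' @param n_cells simulated cells per draw, default 200.
#' @param n_resample sequencing resamples per draw, default 10.
#' @param n_keep lowest-MSE draws retained, default 50.
#' @param log10r_range prior support for log10(r), default (-9, -3).
#' @param L genome length.
#' @param standardize standardize statistics by their across-draw SD before
#'   the MSE (default FALSE; see [infer_turnover_rate()]).
#' @param copy_number optional named per-donor copy numbers.
#' @param donors optional subset of donor ids.
#' @param seed optional seed.
#' @return object of class `mt_rate_fit` with `donors` (per-donor
#'   estimates) and settings.
#' @export
infer_mutation_rate <- function(cohort, classified, turnover_rates,
                                model = c("mitotic", "homeostatic"),
                                n_draws = 1000L, n_cells = 200L,
                                n_resample = 10L, n_keep = 50L,
                                log10r_range = c(-9, -3), L = 16569L,
                                standardize = FALSE, copy_number = NULL,
                                donors = NULL, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  meta <- cohort$clones
  if (is.null(copy_number)) {
    cn <- tapply(mtdna_copy_number(meta$mean_coverage_mt,
                                   meta$mean_coverage_nuclear),
                 meta$donor_id, mean)
  } else cn <- copy_number
  donor_meta <- unique(meta[, c("donor_id", "tissue", "donor_age")])
  if (is.null(donors)) donors <- donor_meta$donor_id
  calls <- cohort$calls
  calls$donor_id <- meta$donor_id[match(calls$clone_id, meta$clone_id)]
  ck <- paste(variant_key(calls), calls$donor_id)
  sk <- paste(paste(classified$position, classified$ref, classified$alt,
                    sep = ":"), classified$donor_id)
  cls <- classified$origin_class[match(ck, sk)]

  rows <- lapply(donors, function(d) {
    dm <- donor_meta[donor_meta$donor_id == d, ]
    if (dm$donor_age <= 0) return(NULL)
    rate <- turnover_rates[[dm$tissue]]
    g <- max(1L, as.integer(round(rate * dm$donor_age)))
    n <- max(2L, as.integer(round(cn[[d]])))
    clones <- meta$clone_id[meta$donor_id == d]
    ledgers <- lapply(clones, function(cid) {
      sel <- !is.na(cls) & cls == "PZ_simple" & calls$clone_id == cid
      calls$vaf[sel]
    })
    obs <- pz_summary_stats(ledgers)
    n_obs <- length(clones)

    log10r <- runif(n_draws, log10r_range[1], log10r_range[2])
    sims <- matrix(0, nrow = n_draws * n_resample, ncol = 22L)
    draw_of_row <- rep(seq_len(n_draws), each = n_resample)
    row <- 1L
    for (i in seq_len(n_draws)) {
      ms <- cpp_lineage_sim(n, as.integer(n_cells), g, 10^log10r[i] * L,
                            if (model == "mitotic") 0L else 1L,
                            integer(0), FALSE, TRUE, n,
                            collect_min = 0.004)
      fl <- ms$final_muts
      for (r_ in seq_len(n_resample)) {
        idx <- sample.int(n_cells, min(n_obs, n_cells))
        sims[row, ] <- pz_summary_stats(fl[idx])
        row <- row + 1L
      }
    }
    mse <- mse_table(obs, sims, n_obs, seq_len(20), standardize)
    keep <- order(mse)[seq_len(min(n_keep, length(mse)))]
    lk <- log10r[draw_of_row[keep]]
    data.frame(donor_id = d, tissue = dm$tissue, donor_age = dm$donor_age,
               n_copy = n, g = g,
               log10_r = mean(lk), r = 10^mean(lk),
               r_min = 10^min(lk), r_max = 10^max(lk),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  structure(list(donors = do.call(rbind, rows), model = model,
                 n_draws = n_draws, n_cells = n_cells,
                 n_resample = n_resample, n_keep = n_keep),
            class = "mt_rate_fit")
}

#' @export
print.mt_rate_fit <- function(x, ...) {
  cat("mt_rate_fit (", x$model, " model): ", nrow(x$donors),
      " donor(s)\n", sep = "")
  for (i in seq_len(nrow(x$donors)))
    cat(sprintf("  %s: r = %.2e per bp per replication (range %.1e-%.1e)\n",
                x$donors$donor_id[i], x$donors$r[i], x$donors$r_min[i],
                x$donors$r_max[i]))
  cat(sprintf("  pooled: r = %.2e\n", 10^mean(x$donors$log10_r)))
  invisible(x)
}

#' @export
coef.mt_rate_fit <- function(object, ...) {
  c(r = 10^mean(object$donors$log10_r))
}

#' Expected de novo mutations per daughter cell per division
#'
#' One cell division replicates all `n` molecules once with per-replication
#' mutation intensity `r * L`, and the doubled pool is split between two
#' daughters: `r * L * n / 2` expected new mutations per daughter.
#'
#' @param r mutation rate per bp per replication.
#' @param L genome length, default 16,569.
#' @param n basal copy number, default 750.
#' @return expected mutation count.
#' @examples
#' expected_mutations_per_division(5e-8) # ~0.31
#' @export
expected_mutations_per_division <- function(r, L = 16569, n = 750) {
  stopifnot(r >= 0, L > 0, n > 0)
  r * L * n / 2
}
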