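#' Configuration for mtDNA drift simulations
#'
#' @param n basal mtDNA copies per cell (default 750, the cohort average).
#' @param p0 initial variant frequency (caVAF proxy).
#' @param g_max number of turnovers to simulate.
#' @param n_cells simultaneously simulated cells, default 10,000.
#' @param r mutation rate per bp per replication event (0 = none).
#' @param L genome length, default 16,569 (rCRS); the per-replication
#'   mutation intensity is `lambda = r * L`.
#' @param model `"mitotic"` (Polya-urn doubling + random halving) or
#'   `"homeostatic"` (n Moran replacement events per turnover).
#' @param events_per_turnover Moran events per homeostatic turnover,
#'   default `n`.
#' @return list of class `mt_drift_config`.
#' @export
drift_config <- function(n = 750L, p0 = 0.1, g_max = 1000L,
                         n_cells = 10000L, r = 0, L = 16569L,
                         model = c("mitotic", "homeostatic"),
                         events_per_turnover = NULL) {
  model <- match.arg(model)
  stopifnot(n >= 2L, p0 >= 0, p0 <= 1, g_max >= 0L, n_cells >= 1L, r >= 0)
  if (is.null(events_per_turnover)) events_per_turnover <- n
  structure(list(n = as.integer(n), p0 = p0, g_max = as.integer(g_max),
                 n_cells = as.integer(n_cells), r = r, L = as.integer(L),
                 model = model,
                 events_per_turnover = as.integer(events_per_turnover)),
            class = "mt_drift_config")
}

#' Simulate neutral drift of a biallelic heteroplasmy
#'
#' Each of `n_cells` cells starts at variant frequency `p0` (variant count
#' `round(p0 * n)`) and undergoes `g_max` turnovers under the chosen model.
#' Frequencies are recorded at the requested turnovers; counts of fixed
#' (frequency 1) and lost (frequency 0) cells are recorded at every
#' turnover.
#'
#' @param config an [drift_config()] object (with `r = 0`).
#' @param record_at integer turnovers at which to record per-cell
#'   frequencies (default: only the final turnover).
#' @param seed optional integer seed.
#' @return object of class `mt_drift`: list with `freq_final`, `freq`
#'   (matrix, length(record_at) x n_cells), `record_at`, `fixed_frac`,
#'   `lost_frac` (per turnover), `fix_time` (per cell, `NA` if not fixed),
#'   `config`.
#' @examples
#' s <- simulate_drift(drift_config(n = 50, p0 = 0.3, g_max = 100,
#'                                  n_cells = 500), seed = 1)
#' summary(s)
#' @export
simulate_drift <- function(config, record_at = NULL, seed = NULL) {
  stopifnot(inherits(config, "mt_drift_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(record_at)) record_at <- config$g_max
  record_at <- sort(unique(as.integer(record_at)))
  stopifnot(all(record_at >= 0L & record_at <= config$g_max))
  k0 <- rep.int(as.integer(round(config$p0 * config$n)), config$n_cells)
  res <- cpp_drift_two_allele(k0, config$n, config$g_max,
                              if (config$model == "mitotic") 0L else 1L,
                              record_at, config$events_per_turnover)
  freq <- res$recorded / config$n
  rownames(freq) <- record_at
  structure(list(freq_final = res$k_final / config$n,
                 freq = freq, record_at = record_at,
                 fixed_frac = res$fixed_count / config$n_cells,
                 lost_frac = res$lost_count / config$n_cells,
                 fix_time = ifelse(res$fix_time < 0, NA_integer_,
                                   res$fix_time),
                 config = config),
            class = "mt_drift")
}

#' @export
print.mt_drift <- function(x, ...) {
  cfg <- x$config
  cat("mt_drift:", cfg$model, "model, n =", cfg$n, ", p0 =", cfg$p0,
      ",", cfg$n_cells, "cells,", cfg$g_max, "turnovers\n")
  cat("  fixed:", round(100 * mean(x$freq_final == 1), 2),
      "% | lost:", round(100 * mean(x$freq_final == 0), 2),
      "% | mean freq:", round(mean(x$freq_final), 4), "\n")
  invisible(x)
}

#' @export
summary.mt_drift <- function(object, ...) {
  print(object)
  cat("  final frequency quantiles:\n")
  print(round(quantile(object$freq_final, c(0, .25, .5, .75, 1)), 4))
  invisible(object)
}

#' @export
plot.mt_drift <- function(x, ...) {
  graphics::hist(x$freq_final, breaks = seq(0, 1, by = 0.05),
                 main = paste(x$config$model, "drift after", x$config$g_max,
                              "turnovers"),
                 xlab = "variant frequency per cell", ...)
  invisible(x)
}

#' Mean turnovers to fixation over a grid of initial frequencies
#'
#' For each `p0`, cells are simulated until `g_max` turnovers and the first
#' turnover at which each cell reaches frequency 1 is recorded.  The mean
#' over fixing cells is reported together with the fixing fraction and a
#' conservative mean with non-fixing cells counted at `g_max`.
#'
#' @param n basal copy number, default 750.
#' @param p0 grid of initial frequencies, default 0.1..0.9.
#' @param n_cells cells per grid point, default 10,000.
#' @param g_max turnover cap, default 10,000.
#' @param model turnover model.
#' @param seed optional seed.
#' @return data.frame with `p0`, `mean_fix_turnovers`, `fixing_frac`,
#'   `mean_fix_capped`, `n_cells`.
#' @export
turnovers_to_fixation <- function(n = 750L, p0 = seq(0.1, 0.9, by = 0.1),
                                  n_cells = 10000L, g_max = 10000L,
                                  model = c("mitotic", "homeostatic"),
                                  seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(p0, function(p) {
    s <- simulate_drift(drift_config(n = n, p0 = p, g_max = g_max,
                                     n_cells = n_cells, model = model))
    ft <- s$fix_time
    data.frame(p0 = p,
               mean_fix_turnovers = mean(ft, na.rm = TRUE),
               fixing_frac = mean(!is.na(ft)),
               mean_fix_capped = mean(ifelse(is.na(ft), g_max, ft)),
               n_cells = n_cells)
  })
  do.call(rbind, res)
}

#' Simulate postzygotic mutation accumulation with molecule tracking
#'
#' All molecules start mutation-free; every replication event acquires
#' `Poisson(r * L)` new infinite-sites mutations on the newly created copy.
#' Per-mutation frequencies follow the full turnover dynamics (mutations
#' created during the doubling phase are subject to the same halving).
#'
#' @inheritParams drift_config
#' @param g number of turnovers.
#' @param record_at turnovers at which to record the per-cell top mutation
#'   frequency.
#' @param track_founders also track founder lineages (all `n` initial
#'   molecules distinct), default FALSE.
#' @param seed optional seed.
#' @return object of class `mt_mutsim`: list with `mut_freqs` (list of
#'   per-cell mutation frequency vectors at turnover `g`), `top_mut`
#'   (matrix, record points x cells), `top_founder` (matrix or NULL),
#'   `record_at`, and the parameters.
#' @export
simulate_mutation_accumulation <- function(n = 750L, n_cells = 1000L,
                                           g = 1000L, r = 5e-8, L = 16569L,
                                           model = c("mitotic", "homeostatic"),
                                           record_at = NULL,
                                           track_founders = FALSE,
                                           seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(record_at)) record_at <- g
  record_at <- sort(unique(as.integer(record_at)))
  res <- cpp_lineage_sim(as.integer(n), as.integer(n_cells), as.integer(g),
                         r * L, if (model == "mitotic") 0L else 1L,
                         record_at, track_founders, TRUE, as.integer(n))
  structure(list(mut_freqs = res$final_muts,
                 top_mut = {m <- res$mut_top; rownames(m) <- record_at; m},
                 top_founder = if (track_founders) {
                   m <- res$founder_top; rownames(m) <- record_at; m
                 } else NULL,
                 record_at = record_at,
                 n = n, n_cells = n_cells, g = g, r = r, L = L,
                 model = model),
            class = "mt_mutsim")
}

#' @export
print.mt_mutsim <- function(x, ...) {
  nm <- vapply(x$mut_freqs, length, integer(1))
  cat("mt_mutsim:", x$model, "model, n =", x$n, ", r =", x$r, ",", x$n_cells,
      "cells,", x$g, "turnovers\n")
  cat("  segregating mutations per cell: mean", round(mean(nm), 2),
      "| cells with a mutation > 0.9:",
      round(100 * mean(vapply(x$mut_freqs, function(f)
        any(f > 0.9), logical(1))), 2), "%\n")
  invisible(x)
}

#' Purification and mutation-expansion contour profiles
#'
#' Tracks every founder molecule (all `n` initially distinct) and,
#' optionally, postzygotic mutations, across turnovers; at each recorded
#' turnover the distribution over cells of (a) the most prevalent founder
#' lineage frequency and (b) the top mutation frequency is emitted in long
#' format for contour plotting.
#'
#' @param n vector of basal copy numbers, default the published grid.
#' @param g turnovers, default 1,000.
#' @param n_cells cells per condition, default 10,000.
#' @param r mutation rate per bp per replication (0 = founder tracking
#'   only).
#' @param L genome length.
#' @param model turnover model.
#' @param record_at turnovers to record, default every 50.
#' @param seed optional seed.
#' @return long data.frame: `n`, `model`, `turnover`, `cell`,
#'   `top_founder_freq`, `top_mut_freq`.
#' @export
purification_profile <- function(n = c(500L, 750L, 1000L, 1500L, 2000L),
                                 g = 1000L, n_cells = 10000L, r = 0,
                                 L = 16569L,
                                 model = c("mitotic", "homeostatic"),
                                 record_at = NULL, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(record_at)) record_at <- seq(0L, g, by = 50L)
  record_at <- sort(unique(as.integer(record_at)))
  out <- lapply(n, function(ni) {
    res <- cpp_lineage_sim(as.integer(ni), as.integer(n_cells),
                           as.integer(g), r * L,
                           if (model == "mitotic") 0L else 1L,
                           record_at, TRUE, FALSE, as.integer(ni))
    data.frame(n = ni, model = model,
               turnover = rep(record_at, times = n_cells),
               cell = rep(seq_len(n_cells), each = length(record_at)),
               top_founder_freq = as.vector(res$founder_top),
               top_mut_freq = as.vector(res$mut_top))
  })
  do.call(rbind, out)
}

#' Molecule-by-molecule oracle for one turnover step
#'
#' Reference implementation of a single turnover operating on an explicit
#' vector of per-class molecule counts, replicating one molecule at a time.
#' Used to validate the beta-binomial/Dirichlet-multinomial doubling and
#' hypergeometric halving shortcut, and the Moran event acceleration;
#' intended for small `n` only.
#'
#' @param counts integer vector of molecule counts per class (sums to `n`).
#' @param model `"mitotic"` or `"homeostatic"`.
#' @param events number of Moran events for the homeostatic model
#'   (default `sum(counts)`).
#' @return integer vector of new per-class counts (sums to `n`).
#' @export
drift_step_oracle <- function(counts, model = c("mitotic", "homeostatic"),
                              events = NULL) {
  model <- match.arg(model)
  n <- sum(counts)
  pool <- rep(seq_along(counts), counts)
  if (model == "mitotic") {
    for (i in seq_len(n)) {
      template <- pool[sample.int(length(pool), 1L)]
      pool <- c(pool, template)
    }
    pool <- pool[sample.int(2L * n, n)]
  } else {
    if (is.null(events)) events <- n
    for (e in seq_len(events)) {
      victim <- sample.int(n, 1L)
      pool <- pool[-victim]
      template <- pool[sample.int(n - 1L, 1L)]
      pool <- c(pool, template)
    }
  }
  tabulate(pool, nbins = length(counts))
}
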