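#' Relative-gap threshold separating background noise from true signal
#'
#' VAFs at one locus across the clone panel are sorted ascending and
#' restricted to the working window (default 0.05\%-15\%).  For each adjacent
#' pair the relative gap `(VAF' - VAF)/VAF` is computed; among pairs with
#' relative gap >= `min_rel_gap` the pair with the largest absolute gap is
#' taken as the noise/signal boundary, and the threshold is
#' `min(mean(VAF, VAF'), VAF * (1 + min_rel_gap))`.  Returns `NA` when no
#' pair qualifies (degenerate or gap-free input).
#'
#' @param vafs numeric vector of per-clone VAFs at one (position, alt).
#' @param vaf_range working window, default `c(0.0005, 0.15)`.
#' @param min_rel_gap minimum qualifying relative gap, default 0.33.
#' @return a single numeric threshold, or `NA_real_`.
#' @examples
#' gap_threshold(c(0.0010, 0.0012, 0.0013, 0.0100)) # 0.0013 * 1.33
#' @export
gap_threshold <- function(vafs, vaf_range = c(0.0005, 0.15),
                          min_rel_gap = 0.33) {
  v <- sort(vafs[vafs >= vaf_range[1] & vafs <= vaf_range[2]])
  if (length(v) < 2L) return(NA_real_)
  lo <- v[-length(v)]
  hi <- v[-1L]
  rel <- (hi - lo) / lo
  qual <- which(rel >= min_rel_gap)
  if (!length(qual)) return(NA_real_)
  j <- qual[which.max((hi - lo)[qual])]
  min(mean(c(lo[j], hi[j])), lo[j] * (1 + min_rel_gap))
}

#' Build the locus-specific background-noise panel
#'
#' For every measured (position, ref, alt) the VAF vector across all panel
#' clones (zeros included) yields the mean, standard deviation, the
#' one-sided 95\% upper bound `mean + 1.645 * sd`, and the relative-gap
#' threshold from [gap_threshold()].
#'
#' @param cohort an `mt_cohort`; all retained clones form the panel (the
#'   clone under evaluation is included, mirroring a panel built from all
#'   normal clones).
#' @param min_clones minimum panel size, default 20.
#' @param sites optional data.frame restricting the panel to given sites.
#' @return an object of class `mt_noise_panel`: a data.frame with columns
#'   `position`, `ref`, `alt`, `mean`, `sd`, `ci_bound`, `gap_threshold`,
#'   plus the panel VAF matrix in `attr(, "vaf_matrix")`.
#' @export
build_noise_panel <- function(cohort, min_clones = 20L, sites = NULL) {
  n_clones <- nrow(cohort$clones)
  if (n_clones < min_clones)
    stop("noise panel requires at least ", min_clones, " clones (got ",
         n_clones, ")")
  M <- site_vaf_matrix(cohort, sites = sites, use = "measurements")
  mu <- rowMeans(M)
  sdv <- apply(M, 1L, sd)
  gt <- apply(M, 1L, gap_threshold)
  key <- strsplit(rownames(M), ":")
  out <- data.frame(position = as.integer(vapply(key, `[`, "", 1L)),
                    ref = vapply(key, `[`, "", 2L),
                    alt = vapply(key, `[`, "", 3L),
                    mean = mu, sd = sdv,
                    ci_bound = mu + stats::qnorm(0.95) * sdv,
                    gap_threshold = gt,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "vaf_matrix") <- M
  class(out) <- c("mt_noise_panel", "data.frame")
  out
}

#' @export
print.mt_noise_panel <- function(x, ...) {
  cat("mt_noise_panel:", nrow(x), "sites over",
      ncol(attr(x, "vaf_matrix")), "panel clones;",
      sum(!is.na(x$gap_threshold)), "with a relative-gap threshold\n")
  invisible(as.data.frame(x))
}

#' Reconcile called variants against the background-noise panel
#'
#' Every (clone, site) measurement is compared with the site's effective
#' threshold: the relative-gap threshold when available, else the one-sided
#' 95\% CI bound.  Called measurements at or below the threshold are removed
#' as false positives; uncalled measurements above it are rescued as false
#' negatives.  The operation is idempotent.
#'
#' @param cohort an `mt_cohort`.
#' @param panel an `mt_noise_panel` built on the same (or a superset of the)
#'   clone set.
#' @param prefer `"gap"` (default) uses the gap threshold with CI fallback;
#'   `"ci"` always uses the CI bound; `"max"` requires a mutant VAF to
#'   exceed both.
#' @param min_rescue_vaf practical detection floor applied to the rescue
#'   path only (default 0.003, the ~0.3\% heteroplasmy resolvable at
#'   several-thousand-fold mtDNA depth): uncalled measurements are rescued
#'   only when above both the site threshold and this floor.  Already
#'   called variants are judged against the site threshold alone.
#' @return the cohort with `calls` replaced by the reconciled set; each call
#'   carries a `reconcile_status` of `kept` or `rescued`, and removed calls
#'   are reported in `attr(cohort$calls, "removed")`.
#' @export
reconcile_calls <- function(cohort, panel, prefer = c("gap", "ci", "max"),
                            min_rescue_vaf = 0.003) {
  prefer <- match.arg(prefer)
  mm <- cohort$measurements
  pk <- variant_key(panel)
  mk <- variant_key(mm)
  idx <- match(mk, pk)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " measurement site(s) absent from panel; ",
            "corresponding calls kept as-is")
  }
  thr <- switch(prefer,
    gap = ifelse(is.na(panel$gap_threshold[idx]), panel$ci_bound[idx],
                 panel$gap_threshold[idx]),
    ci = panel$ci_bound[idx],
    max = pmax(panel$ci_bound[idx], panel$gap_threshold[idx], na.rm = TRUE))
  is_mutant <- !is.na(thr) & mm$vaf > thr
  was_called <- mm$called
  keep <- (was_called & (is.na(thr) | is_mutant)) |
    (!was_called & is_mutant & mm$vaf > min_rescue_vaf)
  calls <- mm[keep, , drop = FALSE]
  calls$called <- TRUE
  calls$reconcile_status <- ifelse(was_called[keep], "kept", "rescued")
  removed <- mm[was_called & !keep, , drop = FALSE]
  attr(calls, "removed") <- removed
  cohort$calls <- calls
  # rescued calls become part of the measurement call state so the
  # operation is idempotent
  cohort$measurements$called <- mk %in% variant_key(calls) &
    paste(mk, mm$clone_id) %in% paste(variant_key(calls), calls$clone_id)
  cohort
}
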