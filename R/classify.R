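#' Maximum-likelihood spontaneous rate and binomial tail probability
#'
#' The spontaneous occurrence rate of a shared variant is estimated from the
#' rest of the cohort by maximum likelihood under a binomial model,
#' `p_hat = x_exp / n`, and the probability that the within-donor sharing
#' arose by chance is the upper binomial tail
#' `P(X >= x_obs)` with `X ~ Binomial(n_obs, p_hat)`.
#'
#' @param x_exp mutant clones among the `n` panel clones (donor excluded).
#' @param n panel clone count.
#' @param x_obs mutant clones within the focal donor.
#' @param n_obs clone count of the focal donor.
#' @return list with `p_hat_ml` and `tail_p`.
#' @examples
#' ml_rate_and_tail(x_exp = 2, n = 2069, x_obs = 14, n_obs = 27)
#' @export
ml_rate_and_tail <- function(x_exp, n, x_obs, n_obs) {
  if (n <= 0 || n_obs <= 0) stop("n and n_obs must be positive")
  if (x_obs == 0) stop("x_obs = 0: nothing to classify")
  p_hat <- x_exp / n
  tail_p <- stats::pbinom(x_obs - 1, n_obs, p_hat, lower.tail = FALSE)
  list(p_hat_ml = p_hat, tail_p = tail_p)
}

# nuclear mutations accumulated from the root to the MRCA of a set of tips
root_to_mrca_depth <- function(tree, tips) {
  tips <- intersect(tips, tree$tip.label)
  if (length(tips) < 2L) return(0)
  mrca <- ape::getMRCA(tree, tips)
  root <- ape::Ntip(tree) + 1L
  if (is.null(mrca) || mrca == root) return(0)
  depth <- 0
  node <- mrca
  while (node != root) {
    e <- which(tree$edge[, 2L] == node)
    depth <- depth + tree$edge.length[e]
    node <- tree$edge[e, 1L]
  }
  depth
}

#' Classify mtDNA variants by developmental origin
#'
#' Assigns each (variant, donor) observation an origin class via the
#' following precedence:
#' \enumerate{
#'   \item `PZ_recurrent`: the site is mutant in >= 2 individuals each with
#'     >= 2 mutant clones, or in at least `min_individuals_full` individuals
#'     (10 on the full 86-individual reference panel, rescaled
#'     proportionally, never below 3).
#'   \item `PZ_simple` (late branch): the donor's mutant clones descend from
#'     a subtree whose ancestor accumulated >= `late_branch_mutations`
#'     nuclear mutations before diverging.
#'   \item `Het_FE`: shared by >= 2 clones of exactly one individual, absent
#'     elsewhere.
#'   \item Shared in one donor, sporadic elsewhere: `Het_FE` when the
#'     binomial tail probability from [ml_rate_and_tail()] is below `alpha`,
#'     else `PZ_simple`.
#'   \item Singleton present in the donor's matched bulk tissue at VAF >=
#'     `blood_min_vaf`: `Het_FE`.
#'   \item Otherwise `PZ_simple`.
#' }
#'
#' @param cohort an `mt_cohort` with reconciled calls.
#' @param alpha binomial decision threshold, default 0.01.
#' @param cohort_size_full reference panel size behind the >=10-individuals
#'   recurrence rule, default 86.
#' @param min_recurrent_individuals override for the cohort-wide recurrence
#'   rule; `NULL` (default) scales 10/86 proportionally to the actual
#'   number of individuals, never below 3.
#' @param late_branch_mutations nuclear-mutation depth defining a late
#'   branch, default 100.
#' @param blood_min_vaf minimum matched-bulk VAF for the singleton rescue,
#'   default 0.005.
#' @return data.frame with one row per (variant, donor): `position`, `ref`,
#'   `alt`, `donor_id`, `n_mutant_clones`, `origin_class`, `tail_p`,
#'   `rule_fired`.
#' @export
classify_variants <- function(cohort, alpha = 0.01, cohort_size_full = 86L,
                              late_branch_mutations = 100,
                              blood_min_vaf = 0.005,
                              min_recurrent_individuals = NULL) {
  calls <- cohort$calls
  meta <- cohort$clones
  calls$donor_id <- meta$donor_id[match(calls$clone_id, meta$clone_id)]
  key <- variant_key(calls)
  donors <- unique(meta$donor_id)
  n_ind <- length(donors)
  min_ind_full <- if (is.null(min_recurrent_individuals))
    max(3L, ceiling(10L * n_ind / cohort_size_full))
  else as.integer(min_recurrent_individuals)
  clones_per_donor <- table(meta$donor_id)

  out <- list()
  for (k in unique(key)) {
    rows <- calls[key == k, , drop = FALSE]
    per_donor <- table(rows$donor_id)
    multi_donors <- sum(per_donor >= 2L)
    recurrent <- multi_donors >= 2L || length(per_donor) >= min_ind_full
    for (d in names(per_donor)) {
      x_obs <- as.integer(per_donor[[d]])
      cls <- NA_character_; rule <- NA_character_; tail_p <- NA_real_
      if (recurrent) {
        cls <- "PZ_recurrent"
        rule <- if (multi_donors >= 2L) "recurrent_multi_donor" else "recurrent_cohort_wide"
      } else if (x_obs >= 2L) {
        late <- FALSE
        tree <- cohort$phylo[[d]]
        if (!is.null(tree)) {
          depth <- root_to_mrca_depth(tree, rows$clone_id[rows$donor_id == d])
          late <- depth >= late_branch_mutations
        } else if (late_branch_mutations < Inf && x_obs >= 2L &&
                   length(cohort$phylo) == 0L) {
          # no phylogeny available anywhere: rule silently unavailable
        } else if (is.null(tree)) {
          warning("no phylogeny for donor ", d, "; late-branch rule skipped")
        }
        x_exp <- sum(per_donor) - x_obs
        n_panel <- sum(clones_per_donor) - clones_per_donor[[d]]
        if (late) {
          cls <- "PZ_simple"; rule <- "late_branch"
        } else if (x_exp == 0L) {
          cls <- "Het_FE"; rule <- "exclusive_shared"; tail_p <- 0
        } else {
          mt <- ml_rate_and_tail(x_exp, n_panel, x_obs, clones_per_donor[[d]])
          tail_p <- mt$tail_p
          if (tail_p < alpha) { cls <- "Het_FE"; rule <- "binomial_tail" }
          else { cls <- "PZ_simple"; rule <- "binomial_tail" }
        }
      } else {
        in_blood <- FALSE
        if (!is.null(cohort$bulk)) {
          b <- cohort$bulk
          bk <- paste(b$position, b$ref, b$alt, sep = ":")
          in_blood <- any(bk == k & b$donor_id == d & b$vaf >= blood_min_vaf)
        }
        if (in_blood) { cls <- "Het_FE"; rule <- "matched_bulk" }
        else { cls <- "PZ_simple"; rule <- "singleton" }
      }
      key3 <- strsplit(k, ":")[[1L]]
      out[[length(out) + 1L]] <- data.frame(
        position = as.integer(key3[1L]), ref = key3[2L], alt = key3[3L],
        donor_id = d, n_mutant_clones = x_obs, origin_class = cls,
        tail_p = tail_p, rule_fired = rule, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Flag tissue-specific recurrent (hotspot) loci
#'
#' A locus is flagged within a tissue when it recurs in at least
#' `min_donors` donors of that tissue and its carrier donors are older than
#' non-carriers by a one-sided Wilcoxon rank-sum test at `alpha` (normal
#' approximation with tie correction when ties are present).
#'
#' @param classified output of [classify_variants()].
#' @param cohort the `mt_cohort`.
#' @param alpha test level, default 0.05.
#' @param min_donors minimum recurrence within the tissue, default 2.
#' @return data.frame of flagged (tissue, position, ref, alt) with carrier
#'   counts and the Wilcoxon p-value.
#' @export
detect_tissue_recurrent <- function(classified, cohort, alpha = 0.05,
                                    min_donors = 2L) {
  meta <- cohort$clones
  donor_meta <- unique(meta[, c("donor_id", "tissue", "donor_age")])
  cl <- merge(classified, donor_meta, by = "donor_id")
  out <- list()
  for (tis in unique(donor_meta$tissue)) {
    dt <- donor_meta[donor_meta$tissue == tis, , drop = FALSE]
    if (nrow(dt) < 2L) next
    sub <- cl[cl$tissue == tis, , drop = FALSE]
    kk <- paste(sub$position, sub$ref, sub$alt, sep = ":")
    for (k in unique(kk)) {
      carriers <- unique(sub$donor_id[kk == k])
      if (length(carriers) < min_donors) next
      age_c <- dt$donor_age[dt$donor_id %in% carriers]
      age_n <- dt$donor_age[!dt$donor_id %in% carriers]
      if (!length(age_n)) next
      p <- suppressWarnings(
        stats::wilcox.test(age_c, age_n, alternative = "greater",
                           exact = FALSE)$p.value)
      if (!is.na(p) && p < alpha) {
        key3 <- strsplit(k, ":")[[1L]]
        out[[length(out) + 1L]] <- data.frame(
          tissue = tis, position = as.integer(key3[1L]), ref = key3[2L],
          alt = key3[3L], n_carrier_donors = length(carriers), p_value = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(tissue = character(), position = integer(),
                      ref = character(), alt = character(),
                      n_carrier_donors = integer(), p_value = numeric()))
  do.call(rbind, out)
}
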