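#' Enumerate the mutational opportunity of a mitochondrial genome
#'
#' Every CDS position times three alternative bases, classified by coding
#' consequence under the vertebrate mitochondrial code.  Individual-specific
#' germline variants can be applied to the sequence beforehand.
#'
#' @param genome an [mt_genome].
#' @param germline optional data.frame of SNVs (`position`, `ref`, `alt`)
#'   substituted into the sequence before enumeration.
#' @return list with `counts` (named: synonymous, missense, truncating) and
#'   `table` (every possible CDS SNV with its consequence).
#' @export
mutation_opportunity <- function(genome, germline = NULL) {
  if (!is.null(germline)) genome <- apply_germline(genome, germline)
  tab <- possible_snvs(genome, cds_only = TRUE)
  cons <- factor(tab$consequence,
                 levels = c("synonymous", "missense", "truncating"))
  list(counts = c(table(cons)), table = tab)
}

apply_germline <- function(genome, germline) {
  s <- strsplit(genome$sequence, "")[[1]]
  ref_obs <- s[germline$position]
  if (any(ref_obs != toupper(germline$ref)))
    stop("germline reference mismatch at position ",
         paste(germline$position[ref_obs != toupper(germline$ref)],
               collapse = ", "))
  s[germline$position] <- toupper(germline$alt)
  mt_genome(paste(s, collapse = ""), genome$annotations,
            dloop = genome$dloop, origin_region = genome$origin_region)
}

# every possible SNV at every (or every CDS) position, annotated
possible_snvs <- function(genome, cds_only = FALSE) {
  L <- genome$length
  if (cds_only) {
    cds <- genome$annotations[genome$annotations$feature == "CDS", , drop = FALSE]
    pos <- sort(unique(unlist(lapply(seq_len(nrow(cds)), function(j)
      region_positions(cds$start[j], cds$end[j], L)))))
  } else pos <- seq_len(L)
  ref <- substring(genome$sequence, pos, pos)
  alts <- c("A", "C", "G", "T")
  tab <- do.call(rbind, lapply(alts, function(a) {
    keep <- ref != a
    data.frame(position = pos[keep], ref = ref[keep], alt = a,
               stringsAsFactors = FALSE)
  }))
  annotate_variants(tab, genome)
}

#' Simulated neutral null for mtDNA dN/dS
#'
#' Places exactly `n_mut` random SNVs on the genome per iteration —
#' uniformly, or weighted by a strand-resolved pyrimidine substitution
#' spectrum — annotates them and records the simulated
#' (missense/synonymous) and (truncating/synonymous) ratios normalized by
#' mutational opportunity.  Iterations with zero synonymous hits are
#' excluded and counted.
#'
#' @param genome an [mt_genome].
#' @param n_mut observed mutation count to match per iteration.
#' @param weights optional named weights over the 12 (pyrimidine type x
#'   strand) categories, names like `"C>T|heavy"`; `NULL` = uniform over
#'   all possible SNVs.
#' @param iterations default 10,000.
#' @param germline optional germline SNVs applied first.
#' @return list with `missense`, `truncating` (numeric null vectors),
#'   `n_excluded`, `opportunity`.
#' @export
simulate_null_dnds <- function(genome, n_mut, weights = NULL,
                               iterations = 10000L, germline = NULL) {
  if (n_mut < 1) stop("observed mutation count must be >= 1")
  if (!is.null(germline)) genome <- apply_germline(genome, germline)
  all_snv <- possible_snvs(genome, cds_only = FALSE)
  opp <- table(factor(all_snv$consequence,
                      levels = c("synonymous", "missense", "truncating")))
  if (opp["synonymous"] == 0) stop("genome admits no synonymous change")
  opp_ratio_mis <- opp[["missense"]] / opp[["synonymous"]]
  opp_ratio_tru <- opp[["truncating"]] / opp[["synonymous"]]
  w <- rep(1, nrow(all_snv))
  if (!is.null(weights)) {
    cat_ <- paste(pyrimidine_type(all_snv$ref, all_snv$alt),
                  all_snv$strand_class, sep = "|")
    w <- weights[cat_]
    w[is.na(w)] <- 0
    if (all(w == 0)) stop("weights eliminate every possible SNV")
  }
  w <- w / sum(w)
  cons <- all_snv$consequence
  mis <- tru <- numeric(iterations)
  excluded <- 0L
  for (it in seq_len(iterations)) {
    idx <- sample.int(nrow(all_snv), n_mut, replace = TRUE, prob = w)
    cc <- cons[idx]
    ns <- sum(cc == "synonymous")
    if (ns == 0L) {
      mis[it] <- NA_real_; tru[it] <- NA_real_
      excluded <- excluded + 1L
      next
    }
    mis[it] <- (sum(cc == "missense") / ns) / opp_ratio_mis
    tru[it] <- if (opp_ratio_tru > 0)
      (sum(cc == "truncating") / ns) / opp_ratio_tru else NA_real_
  }
  list(missense = mis[!is.na(mis)], truncating = tru[!is.na(tru)],
       n_excluded = excluded,
       opportunity = c(opp))
}

#' Per-tissue dN/dS report with simulated null and clone-VAF contrast
#'
#' Pools annotated PZ_simple SNVs per tissue, computes
#' opportunity-normalized missense and truncating dN/dS, simulates the
#' neutral null at the observed per-tissue mutation count, and contrasts
#' the clone-VAF distributions of synonymous versus truncating mutations
#' (VAF >= 0.1 only) with a two-sided Fisher's exact test on the
#' proportion exceeding 0.9 VAF.
#'
#' @param cohort an `mt_cohort`.
#' @param classified output of [classify_variants()].
#' @param genome an [mt_genome].
#' @param iterations null iterations per tissue, default 10,000.
#' @param weighted use the observed strand-resolved spectrum as placement
#'   weights (default TRUE; FALSE = uniform placement).
#' @return object of class `mt_dnds`: per-tissue list with observed ratios,
#'   null quartiles and percentile of the observed value, and the Fisher
#'   test.
#' @export
dnds_report <- function(cohort, classified, genome, iterations = 10000L,
                        weighted = TRUE) {
  meta <- cohort$clones
  calls <- cohort$calls
  calls$donor_id <- meta$donor_id[match(calls$clone_id, meta$clone_id)]
  calls$tissue <- meta$tissue[match(calls$clone_id, meta$clone_id)]
  ck <- paste(variant_key(calls), calls$donor_id)
  sk <- paste(paste(classified$position, classified$ref, classified$alt,
                    sep = ":"), classified$donor_id)
  calls$origin_class <- classified$origin_class[match(ck, sk)]
  pz <- calls[!is.na(calls$origin_class) & calls$origin_class == "PZ_simple" &
                nchar(calls$ref) == 1L & nchar(calls$alt) == 1L, , drop = FALSE]
  if (!nrow(pz))
    return(structure(list(tissues = list(), genome = genome),
                     class = "mt_dnds"))
  pz <- annotate_variants(pz, genome)
  weights <- NULL
  if (weighted) {
    cat_ <- paste(pyrimidine_type(pz$ref, pz$alt), pz$strand_class, sep = "|")
    weights <- table(cat_)
    weights <- setNames(as.numeric(weights), names(weights))
  }
  opp <- mutation_opportunity(genome)$counts
  tissues <- lapply(split(pz, pz$tissue), function(sub) {
    # unique variants per (variant, donor) event for the ratio
    uv <- unique(sub[, c("position", "ref", "alt", "donor_id", "consequence")])
    ns <- sum(uv$consequence == "synonymous")
    nm <- sum(uv$consequence == "missense")
    nt <- sum(uv$consequence == "truncating")
    obs_mis <- if (ns > 0) (nm / ns) / (opp[["missense"]] / opp[["synonymous"]]) else NA_real_
    obs_tru <- if (ns > 0 && opp[["truncating"]] > 0)
      (nt / ns) / (opp[["truncating"]] / opp[["synonymous"]]) else NA_real_
    null <- simulate_null_dnds(genome, nrow(uv), weights = weights,
                               iterations = iterations)
    hi <- sub[sub$vaf >= 0.1, , drop = FALSE]
    fisher <- NULL
    syn_hi <- hi$vaf[hi$consequence == "synonymous"]
    tru_hi <- hi$vaf[hi$consequence == "truncating"]
    if (length(syn_hi) && length(tru_hi)) {
      m <- rbind(c(sum(syn_hi > 0.9), sum(syn_hi <= 0.9)),
                 c(sum(tru_hi > 0.9), sum(tru_hi <= 0.9)))
      fisher <- stats::fisher.test(m)
    }
    list(n_syn = ns, n_mis = nm, n_tru = nt,
         dnds_missense = obs_mis, dnds_truncating = obs_tru,
         null_missense_iqr = quantile(null$missense, c(0.25, 0.75)),
         null_truncating_iqr = if (length(null$truncating))
           quantile(null$truncating, c(0.25, 0.75)) else c(NA, NA),
         pct_missense = if (!is.na(obs_mis))
           mean(null$missense <= obs_mis) else NA_real_,
         pct_truncating = if (!is.na(obs_tru) && length(null$truncating))
           mean(null$truncating <= obs_tru) else NA_real_,
         fisher_homoplasmy = fisher,
         n_null_excluded = null$n_excluded)
  })
  structure(list(tissues = tissues, opportunity = opp, weighted = weighted),
            class = "mt_dnds")
}

#' @export
print.mt_dnds <- function(x, ...) {
  if (!length(x$tissues)) {
    cat("mt_dnds: no PZ_simple SNVs\n")
    return(invisible(x))
  }
  cat("mt_dnds (", if (isTRUE(x$weighted)) "spectrum-weighted" else "uniform",
      " null)\n", sep = "")
  for (tn in names(x$tissues)) {
    t_ <- x$tissues[[tn]]
    cat(sprintf("  %s: syn/mis/tru = %d/%d/%d | dN/dS mis %.2f (null IQR %.2f-%.2f), tru %s\n",
                tn, t_$n_syn, t_$n_mis, t_$n_tru, t_$dnds_missense,
                t_$null_missense_iqr[1], t_$null_missense_iqr[2],
                if (is.na(t_$dnds_truncating)) "NA"
                else sprintf("%.2f", t_$dnds_truncating)))
    if (!is.null(t_$fisher_homoplasmy))
      cat(sprintf("    homoplasmy contrast (syn vs tru, VAF>=0.1): p = %.4g\n",
                  t_$fisher_homoplasmy$p.value))
  }
  invisible(x)
}
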