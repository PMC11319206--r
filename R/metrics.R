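#' Clone-averaged VAF (caVAF)
#'
#' Arithmetic mean of a variant's clone-VAF over all clones of a donor,
#' zeros included; an estimator of the fertilized-egg heteroplasmy level.
#'
#' @param vafs clone-VAFs over every clone of the donor (include zeros).
#' @return a fraction in [0, 1].
#' @examples
#' cavaf(c(1, 1, 0, 0)) # 0.5
#' @export
cavaf <- function(vafs) {
  if (!length(vafs)) stop("at least one clone required")
  mean(vafs)
}

#' Fixation index of clone-VAFs
#'
#' Wright's F_ST applied to a variant's clone-VAF distribution:
#' `F_ST = sigma_S^2 / (P_bar (1 - P_bar))`, where `sigma_S^2` is the
#' population variance (divide by N) of clone-VAFs within the donor and
#' `P_bar` the caVAF.  Computed only when `P_bar > 0.01`; below that the
#' result is marked not computed.
#'
#' @param vafs clone-VAFs over every clone of the donor (include zeros).
#' @return list with `p_bar`, `sigma_s_sq`, `sigma_t_sq`, `fst` (`NA` when
#'   not computed) and `computed`.
#' @examples
#' fst_index(c(0.2, 0.4, 0.6))
#' @export
fst_index <- function(vafs) {
  p_bar <- mean(vafs)
  sigma_s_sq <- mean((vafs - p_bar)^2)
  sigma_t_sq <- p_bar * (1 - p_bar)
  if (p_bar <= 0.01)
    return(list(p_bar = p_bar, sigma_s_sq = sigma_s_sq,
                sigma_t_sq = sigma_t_sq, fst = NA_real_, computed = FALSE))
  list(p_bar = p_bar, sigma_s_sq = sigma_s_sq, sigma_t_sq = sigma_t_sq,
       fst = sigma_s_sq / sigma_t_sq, computed = TRUE)
}

#' Per-clone heteroplasmy burden metrics (S_VAF)
#'
#' `S_VAF` is the sum of clone-VAFs of all detected PZ_simple mutations in a
#' clone (Het_FE and PZ_recurrent excluded); also reports the maximum
#' clone-VAF and the number of nearly homoplasmic mutations (clone-VAF >
#' 0.9).
#'
#' @param cohort an `mt_cohort`.
#' @param classified output of [classify_variants()].
#' @return data.frame with one row per retained clone: `clone_id`, `s_vaf`,
#'   `max_clone_vaf`, `n_homoplasmic`, `n_pz_simple`.
#' @export
compute_svaf <- function(cohort, classified) {
  calls <- cohort$calls
  meta <- cohort$clones
  calls$donor_id <- meta$donor_id[match(calls$clone_id, meta$clone_id)]
  ck <- paste(variant_key(calls), calls$donor_id)
  sk <- paste(paste(classified$position, classified$ref, classified$alt,
                    sep = ":"), classified$donor_id)
  cls <- classified$origin_class[match(ck, sk)]
  pz <- !is.na(cls) & cls == "PZ_simple"
  res <- lapply(meta$clone_id, function(cid) {
    v <- calls$vaf[pz & calls$clone_id == cid]
    data.frame(clone_id = cid,
               s_vaf = sum(v),
               max_clone_vaf = if (length(v)) max(v) else 0,
               n_homoplasmic = sum(v > 0.9),
               n_pz_simple = length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' caVAF for every classified Het_FE variant
#'
#' @param cohort an `mt_cohort`.
#' @param classified output of [classify_variants()].
#' @param class origin class to summarise, default `"Het_FE"`.
#' @return data.frame with `position`, `ref`, `alt`, `donor_id`, `cavaf`,
#'   `fst`, `n_clones`.
#' @export
compute_cavaf <- function(cohort, classified, class = "Het_FE") {
  sel <- classified[classified$origin_class == class, , drop = FALSE]
  meta <- cohort$clones
  calls <- cohort$calls
  calls$donor_id <- meta$donor_id[match(calls$clone_id, meta$clone_id)]
  out <- lapply(seq_len(nrow(sel)), function(i) {
    d <- sel$donor_id[i]
    clones <- meta$clone_id[meta$donor_id == d]
    hit <- calls$position == sel$position[i] & calls$ref == sel$ref[i] &
      calls$alt == sel$alt[i] & calls$donor_id == d
    v <- setNames(rep(0, length(clones)), clones)
    v[calls$clone_id[hit]] <- calls$vaf[hit]
    f <- fst_index(unname(v))
    data.frame(position = sel$position[i], ref = sel$ref[i],
               alt = sel$alt[i], donor_id = d, cavaf = mean(v),
               fst = f$fst, n_clones = length(clones),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.PYR_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# pyrimidine-based substitution type and pyrimidine strand of an SNV
pyrimidine_type <- function(ref, alt) {
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, unname(.COMPLEMENT[ref]), ref)
  a <- ifelse(flip, unname(.COMPLEMENT[alt]), alt)
  paste0(r, ">", a)
}

#' Strand-resolved mutational spectrum
#'
#' Counts SNVs by pyrimidine-based substitution type (C>A, C>G, C>T, T>A,
#' T>C, T>G) and the strand of the mutated pyrimidine (heavy/light), split
#' inside versus outside the heavy-strand replication-origin region.
#' Reports per-type log2(heavy/light) ratios per region, and a Pearson
#' chi-squared test comparing spectra across tissues when tissue labels are
#' supplied.
#'
#' @param variants data.frame of annotated SNVs with `strand_class` and
#'   `in_origin` (from [annotate_variants()]); an optional `tissue` column
#'   enables the cross-tissue test.
#' @param pseudocount added to both strands before the log2 ratio (default 0
#'   = ratios with a zero denominator are `NA`).
#' @return object of class `mt_spectrum`: list with `counts` (type x strand
#'   x region array), `log2_ratio` (type x region), `chisq` (htest or NULL).
#' @export
strand_spectrum <- function(variants, pseudocount = 0) {
  snv <- variants[variants$variant_type == "SNV", , drop = FALSE]
  type <- factor(pyrimidine_type(snv$ref, snv$alt), levels = .PYR_TYPES)
  strand <- factor(snv$strand_class, levels = c("heavy", "light"))
  region <- factor(ifelse(snv$in_origin, "origin", "outside"),
                   levels = c("outside", "origin"))
  counts <- table(type, strand, region)
  l2 <- apply(counts, 3L, function(m) {
    h <- m[, "heavy"] + pseudocount
    l <- m[, "light"] + pseudocount
    ifelse(l > 0 & h > 0, log2(h / l), NA_real_)
  })
  chisq <- NULL
  if (!is.null(snv$tissue) && length(unique(snv$tissue)) > 1L) {
    tab <- table(snv$tissue, paste(type, strand))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    chisq <- suppressWarnings(stats::chisq.test(tab))
  }
  structure(list(counts = counts, log2_ratio = l2, chisq = chisq,
                 n_snv = nrow(snv)),
            class = "mt_spectrum")
}

#' @export
print.mt_spectrum <- function(x, ...) {
  cat("mt_spectrum:", x$n_snv, "SNVs\n")
  cat("log2(heavy/light) by region:\n")
  print(round(x$log2_ratio, 3))
  if (!is.null(x$chisq))
    cat("cross-tissue chi-squared: X2 =", round(x$chisq$statistic, 2),
        ", p =", format(x$chisq$p.value, digits = 3), "\n")
  invisible(x)
}
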