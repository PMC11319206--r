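#' Default read-level QC thresholds for mtDNA variant calls
#'
#' Thresholds follow the published filter criteria literally: strict
#' inequalities, so boundary values (mapq 25, baseq 15, position fraction
#' 0.15/0.85, forward fraction 0.10/0.90) pass, while 5 mismatches fails.
#'
#' @return a named list of thresholds and blacklists.
#' @export
mt_filter_thresholds <- function() {
  list(min_mapq = 25, min_baseq = 15,
       position_fraction = c(0.15, 0.85),
       forward_fraction = c(0.10, 0.90),
       max_mismatches = 5,
       indel_max_frac_additional = 0.5,
       blacklist = rbind(c(302L, 315L), c(513L, 525L),
                         c(3105L, 3109L), c(16182L, 16187L)),
       indel_blacklist = c(567L, 955L, 5894L))
}

#' Apply per-variant read-support QC filters
#'
#' One row per (clone, variant) with read-support summaries; the verdict
#' lists every triggered reason code:
#' `mapq`, `baseq`, `position`, `strand`, `mismatches`, `pairing`,
#' `blacklist`, `indel_noise`, `indel_locus`.
#'
#' @param support data.frame with columns `position`, `variant_type`
#'   (`SNV`/`insertion`/`deletion`), `mean_mapq`, `mean_baseq`,
#'   `mean_position_fraction`, `forward_fraction`, `max_mismatches`,
#'   `pairing_ok`, and for InDels `frac_additional_indels`.
#' @param thresholds from [mt_filter_thresholds()].
#' @return the input with logical `pass` and character `reasons`
#'   (semicolon-separated) appended.
#' @export
apply_read_filters <- function(support, thresholds = mt_filter_thresholds()) {
  need <- c("position", "variant_type", "mean_mapq", "mean_baseq",
            "mean_position_fraction", "forward_fraction", "max_mismatches",
            "pairing_ok")
  miss <- setdiff(need, names(support))
  if (length(miss)) stop("support missing column(s): ", paste(miss, collapse = ", "))
  is_indel <- support$variant_type %in% c("insertion", "deletion")
  if (any(is_indel) && is.null(support$frac_additional_indels))
    stop("frac_additional_indels required for InDel rows")
  th <- thresholds
  n <- nrow(support)
  reasons <- vector("list", n)
  add <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    for (i in which(cond)) reasons[[i]] <<- c(reasons[[i]], code)
  }
  add(support$mean_mapq < th$min_mapq, "mapq")
  add(support$mean_baseq < th$min_baseq, "baseq")
  add(support$mean_position_fraction < th$position_fraction[1] |
      support$mean_position_fraction > th$position_fraction[2], "position")
  add(support$forward_fraction < th$forward_fraction[1] |
      support$forward_fraction > th$forward_fraction[2], "strand")
  add(support$max_mismatches >= th$max_mismatches, "mismatches")
  add(!support$pairing_ok, "pairing")
  in_bl <- rep(FALSE, n)
  for (r in seq_len(nrow(th$blacklist)))
    in_bl <- in_bl | (support$position >= th$blacklist[r, 1] &
                      support$position <= th$blacklist[r, 2])
  add(in_bl, "blacklist")
  if (any(is_indel)) {
    add(is_indel & support$frac_additional_indels > th$indel_max_frac_additional,
        "indel_noise")
    add(is_indel & support$position %in% th$indel_blacklist, "indel_locus")
  }
  support$pass <- lengths(reasons) == 0L
  support$reasons <- vapply(reasons, function(r)
    if (length(r)) paste(r, collapse = ";") else "", character(1))
  support
}
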