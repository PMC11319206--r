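#' Load a clone cohort from variant files and a metadata table
#'
#' Reads per-clone mtDNA variant measurements (a long-format TSV or a set of
#' per-clone VCFs), clone metadata, and optional donor phylogenies and bulk
#' tissue VAFs, applying the clonality filter: clones are retained only when
#' `nuclear_clonality_vaf > 0.4` and `mean_coverage_nuclear > 10`.  Excluded
#' clones are reported via a message and kept in `attr(, "excluded")`.
#'
#' Variant input dialects:
#' \describe{
#'   \item{TSV}{columns `clone_id`, `position`, `ref`, `alt`, `vaf` and
#'     optionally `alt_count`, `depth`, `called` (logical; default TRUE).
#'     Rows may carry sub-threshold background measurements
#'     (`called = FALSE`), which feed the noise panel.}
#'   \item{VCF}{one file per clone (clone id = file name without extension,
#'     or the single sample name when present).  VAF is taken from the AD
#'     format field as alt/(ref+alt) when present, else from an AF field;
#'     the choice is reported per file.}
#' }
#'
#' @param variant_files path to one TSV, or character vector of VCF paths.
#' @param metadata path to a TSV with columns `clone_id`, `donor_id`,
#'   `tissue`, `donor_age`, `mean_coverage_nuclear`, `mean_coverage_mt`,
#'   `nuclear_clonality_vaf`.
#' @param trees optional named character vector of Newick paths (names =
#'   donor ids), or a directory containing `<donor_id>.nwk` files.
#' @param bulk optional TSV path with columns `donor_id`, `tissue`,
#'   `position`, `ref`, `alt`, `vaf`.
#' @return an object of class `mt_cohort` with elements `clones`,
#'   `measurements` (all measured VAFs incl. background), `calls`
#'   (measurements with `called = TRUE`), `phylo` (named list of `ape::phylo`
#'   with branch lengths in nuclear mutation counts), `bulk`.
#' @export
load_cohort <- function(variant_files, metadata, trees = NULL, bulk = NULL) {
  meta <- read.delim(metadata, stringsAsFactors = FALSE)
  need <- c("clone_id", "donor_id", "tissue", "donor_age",
            "mean_coverage_nuclear", "mean_coverage_mt",
            "nuclear_clonality_vaf")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))

  keep <- meta$nuclear_clonality_vaf > 0.4 & meta$mean_coverage_nuclear > 10
  excluded <- meta$clone_id[!keep]
  if (length(excluded))
    message("excluding ", length(excluded), " clone(s) failing clonality/coverage filter: ",
            paste(excluded, collapse = ", "))
  meta <- meta[keep, , drop = FALSE]

  if (length(variant_files) == 1L && grepl("\\.tsv$|\\.txt$", variant_files)) {
    mm <- read.delim(variant_files, stringsAsFactors = FALSE)
    if (is.null(mm$called)) mm$called <- TRUE
  } else {
    mm <- do.call(rbind, lapply(variant_files, read_clone_vcf))
    mm$called <- TRUE
  }
  unknown <- setdiff(unique(mm$clone_id), c(meta$clone_id, excluded))
  if (length(unknown))
    stop("clone(s) in variant files absent from metadata: ",
         paste(unknown, collapse = ", "))
  mm <- mm[mm$clone_id %in% meta$clone_id, , drop = FALSE]
  if (any(mm$vaf < 0 | mm$vaf > 1)) stop("VAFs outside [0, 1]")

  phylo <- list()
  if (!is.null(trees)) {
    if (length(trees) == 1L && dir.exists(trees)) {
      fl <- list.files(trees, pattern = "\\.nwk$", full.names = TRUE)
      trees <- setNames(fl, sub("\\.nwk$", "", basename(fl)))
    }
    phylo <- lapply(trees, ape::read.tree)
    if (is.null(names(phylo))) stop("trees must be named by donor id")
  }
  bulk_df <- NULL
  if (!is.null(bulk)) bulk_df <- read.delim(bulk, stringsAsFactors = FALSE)

  out <- structure(list(clones = meta,
                        measurements = mm,
                        calls = mm[mm$called, , drop = FALSE],
                        phylo = phylo,
                        bulk = bulk_df),
                   class = "mt_cohort")
  attr(out, "excluded") <- excluded
  out
}

read_clone_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  clone <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  if (ncol(v@gt) >= 2L) clone <- colnames(v@gt)[2L]
  ad <- tryCatch(vcfR::extract.gt(v, "AD"), error = function(e) NULL)
  if (!is.null(ad) && !all(is.na(ad))) {
    parts <- strsplit(ad[, 1L], ",")
    refn <- as.numeric(vapply(parts, `[`, "", 1L))
    altn <- as.numeric(vapply(parts, `[`, "", 2L))
    vaf <- ifelse(refn + altn > 0, altn / (refn + altn), 0)
    depth <- refn + altn
    message(basename(path), ": VAF from AD field")
  } else {
    af <- vcfR::extract.gt(v, "AF")
    if (is.null(af) || all(is.na(af))) stop("no AD or AF field in ", path)
    vaf <- as.numeric(af[, 1L])
    altn <- NA_real_; depth <- NA_real_
    message(basename(path), ": VAF from AF field")
  }
  data.frame(clone_id = clone,
             position = as.integer(fix$POS),
             ref = fix$REF, alt = fix$ALT,
             vaf = vaf, alt_count = altn, depth = depth,
             stringsAsFactors = FALSE)
}

#' @export
print.mt_cohort <- function(x, ...) {
  cat("mt_cohort:", nrow(x$clones), "clones,",
      length(unique(x$clones$donor_id)), "donors,",
      nrow(x$calls), "called variant observations\n")
  tt <- table(x$clones$tissue)
  cat("  tissues:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  if (length(x$phylo)) cat("  phylogenies for", length(x$phylo), "donor(s)\n")
  invisible(x)
}

#' @export
summary.mt_cohort <- function(object, ...) {
  per_clone <- table(factor(object$calls$clone_id,
                            levels = object$clones$clone_id))
  cat("clones per donor:\n")
  print(table(object$clones$donor_id))
  cat("called variants per clone: mean", round(mean(per_clone), 2),
      "range", paste(range(per_clone), collapse = "-"), "\n")
  invisible(object)
}

#' Write a cohort back to the plain-text formats load_cohort() reads
#'
#' @param cohort an `mt_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cohort$clones, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mm <- cohort$measurements
  mm$vaf <- sprintf("%.17g", mm$vaf) # full precision: round-trips bitwise
  write.table(mm, file.path(dir, "measurements.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(cohort$phylo)) {
    td <- file.path(dir, "trees")
    dir.create(td, showWarnings = FALSE)
    for (d in names(cohort$phylo))
      ape::write.tree(cohort$phylo[[d]], file.path(td, paste0(d, ".nwk")))
  }
  if (!is.null(cohort$bulk))
    write.table(cohort$bulk, file.path(dir, "bulk.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_clones = nrow(cohort$clones),
         n_donors = length(unique(cohort$clones$donor_id)),
         n_measurements = nrow(cohort$measurements),
         n_called = sum(cohort$measurements$called),
         written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Reload a cohort written by write_cohort()
#' @param dir directory produced by [write_cohort()].
#' @return an `mt_cohort`.
#' @export
read_cohort_dir <- function(dir) {
  trees <- NULL
  td <- file.path(dir, "trees")
  if (dir.exists(td)) trees <- td
  bulk <- file.path(dir, "bulk.tsv")
  load_cohort(file.path(dir, "measurements.tsv"),
              file.path(dir, "metadata.tsv"),
              trees = trees,
              bulk = if (file.exists(bulk)) bulk else NULL)
}

# variant identity key used across the package
variant_key <- function(df) paste(df$position, df$ref, df$alt, sep = ":")

#' Per-clone VAF matrix at a set of sites (zeros for unmeasured clones)
#'
#' @param cohort an `mt_cohort`.
#' @param sites optional data.frame with `position`, `ref`, `alt`; defaults
#'   to all measured sites.
#' @param use one of "measurements" or "calls".
#' @return numeric matrix, rows = `position:ref:alt` keys, columns = clones.
#' @export
site_vaf_matrix <- function(cohort, sites = NULL,
                            use = c("measurements", "calls")) {
  use <- match.arg(use)
  mm <- cohort[[use]]
  if (is.null(sites)) {
    sites <- unique(mm[, c("position", "ref", "alt")])
  }
  keys <- variant_key(sites)
  clones <- cohort$clones$clone_id
  M <- matrix(0, nrow = length(keys), ncol = length(clones),
              dimnames = list(keys, clones))
  mk <- variant_key(mm)
  ok <- mk %in% keys & mm$clone_id %in% clones
  M[cbind(mk[ok], mm$clone_id[ok])] <- mm$vaf[ok]
  M
}
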