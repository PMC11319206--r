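#' Mitochondrial genome with gene annotations
#'
#' Builds an `mt_genome` object: a circular nucleotide sequence plus 1-based
#' inclusive gene annotations.  Features whose `start > end` wrap around the
#' coordinate origin, matching the m.16,197-191 style of mitochondrial
#' coordinates.  The reference sequence is taken to be the light strand (the
#' C-rich strand of human mtDNA), which fixes the strand assignment of
#' mutated pyrimidines.
#'
#' @param sequence single character string of A/C/G/T (circular).
#' @param annotations data.frame with columns `name`, `start`, `end`,
#'   `strand` (`"+"` = coded on the reference strand, `"-"` = complement) and
#'   `feature` (one of `"CDS"`, `"tRNA"`, `"rRNA"`, `"noncoding"`).
#' @param dloop,origin_region length-2 integer vectors (start, end) of the
#'   D-loop and the heavy-strand replication-origin region; both may wrap.
#'   Defaults are the rCRS coordinates.
#' @return an object of class `mt_genome`.
#' @examples
#' g <- generate_toy_genome(seed = 1)
#' g
#' @export
mt_genome <- function(sequence, annotations,
                      dloop = c(16024L, 576L),
                      origin_region = c(16197L, 191L)) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L <= 0L) stop("empty genome sequence")
  if (grepl("[^ACGT]", sequence)) stop("sequence contains non-ACGT characters")
  need <- c("name", "start", "end", "strand", "feature")
  if (!all(need %in% names(annotations)))
    stop("annotations must have columns: ", paste(need, collapse = ", "))
  if (any(annotations$start < 1L | annotations$start > L |
          annotations$end < 1L | annotations$end > L))
    stop("annotation coordinates outside [1, L]")
  if (!all(annotations$feature %in% c("CDS", "tRNA", "rRNA", "noncoding")))
    stop("unknown feature type in annotations")
  structure(list(sequence = sequence, length = L,
                 annotations = annotations,
                 dloop = as.integer(dloop),
                 origin_region = as.integer(origin_region)),
            class = "mt_genome")
}

#' @export
print.mt_genome <- function(x, ...) {
  cat("mt_genome: circular,", x$length, "bp,", nrow(x$annotations),
      "annotated features\n")
  ft <- table(x$annotations$feature)
  cat(" ", paste(names(ft), ft, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

# unwrap a possibly origin-wrapping 1-based inclusive interval into positions
region_positions <- function(start, end, L) {
  if (start <= end) seq.int(start, end) else c(seq.int(start, L), seq.int(1L, end))
}

#' Test membership of positions in a (possibly wrapping) region
#' @param pos integer positions (1-based).
#' @param region length-2 (start, end); `start > end` wraps the origin.
#' @param L genome length.
#' @return logical vector.
#' @export
in_region <- function(pos, region, L) {
  s <- region[1]; e <- region[2]
  if (s <= e) pos >= s & pos <= e else pos >= s | pos <= e
}

genome_base <- function(genome, pos) {
  substring(genome$sequence, pos, pos)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_base <- function(b) unname(.COMPLEMENT[b])

revcomp <- function(s) {
  paste(rev(unname(.COMPLEMENT[strsplit(s, "")[[1]]])), collapse = "")
}

# vertebrate mitochondrial genetic code, fetched once from Biostrings
.mito_code_env <- new.env(parent = emptyenv())
mito_code <- function() {
  if (is.null(.mito_code_env$code))
    .mito_code_env$code <- Biostrings::getGeneticCode("2")
  .mito_code_env$code
}

translate_mito <- function(cds) {
  # pad incomplete terminal codons with A (polyadenylation-completed stops)
  pad <- (3L - nchar(cds) %% 3L) %% 3L
  cds <- paste0(cds, strrep("A", pad))
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  paste(unname(mito_code()[codons]), collapse = "")
}

# coding-orientation positions of a CDS annotation row (5' -> 3')
cds_positions <- function(ann_row, L) {
  p <- region_positions(ann_row$start, ann_row$end, L)
  if (ann_row$strand == "-") rev(p) else p
}

#' Annotate mtDNA variants with consequence, strand class and region flags
#'
#' For SNVs inside a CDS the reference and mutated codons are translated
#' under the vertebrate mitochondrial genetic code; stop-gains (and
#' frameshift InDels inside a CDS) are `truncating`.  `strand_class` is the
#' strand carrying the mutated pyrimidine: `light` when the reference allele
#' is a pyrimidine (the reference sequence being the light strand), `heavy`
#' otherwise.  Incomplete mitochondrial stop codons are completed with A
#' before translation.
#'
#' @param variants data.frame with columns `position`, `ref`, `alt` and
#'   optionally `variant_type` (inferred from allele lengths when absent).
#' @param genome an [mt_genome].
#' @return the input data.frame with columns `variant_type`, `consequence`,
#'   `strand_class`, `in_dloop`, `in_origin` added.
#' @examples
#' g <- generate_toy_genome(seed = 1)
#' v <- data.frame(position = 10L, ref = substring(g$sequence, 10, 10), alt = "T")
#' if (v$ref != "T") annotate_variants(v, g)
#' @export
annotate_variants <- function(variants, genome) {
  stopifnot(all(c("position", "ref", "alt") %in% names(variants)))
  L <- genome$length
  if (any(variants$position < 1L | variants$position > L))
    stop("variant position outside [1, ", L, "]")
  if (is.null(variants$variant_type)) {
    variants$variant_type <- ifelse(
      nchar(variants$ref) == 1L & nchar(variants$alt) == 1L, "SNV",
      ifelse(nchar(variants$alt) > nchar(variants$ref), "insertion", "deletion"))
  }
  ref_obs <- substring(genome$sequence, variants$position,
                       variants$position + nchar(variants$ref) - 1L)
  bad <- which(ref_obs != toupper(variants$ref))
  if (length(bad))
    stop("reference allele mismatch at position ",
         paste(variants$position[bad], collapse = ", "))
  n <- nrow(variants)
  consequence <- character(n)
  strand_class <- rep(NA_character_, n)
  cds <- genome$annotations[genome$annotations$feature == "CDS", , drop = FALSE]
  for (i in seq_len(n)) {
    pos <- variants$position[i]
    type <- variants$variant_type[i]
    if (type == "SNV")
      strand_class[i] <- if (variants$ref[i] %in% c("C", "T")) "light" else "heavy"
    cons <- NA_character_
    sev <- 0L # severity rank across overlapping genes
    for (j in seq_len(nrow(cds))) {
      p <- cds_positions(cds[j, ], L)
      idx <- match(pos, p)
      if (is.na(idx)) next
      if (type != "SNV") {
        len_change <- abs(nchar(variants$alt[i]) - nchar(variants$ref[i]))
        cj <- if (len_change %% 3L != 0L) "truncating" else "missense"
      } else {
        bases <- substring(genome$sequence, p, p)
        if (cds[j, ]$strand == "-") bases <- unname(.COMPLEMENT[bases])
        ref_codon_start <- idx - (idx - 1L) %% 3L
        alt_b <- variants$alt[i]
        if (cds[j, ]$strand == "-") alt_b <- complement_base(alt_b)
        old <- bases
        new <- bases
        new[idx] <- alt_b
        aa_old <- translate_mito(paste(old[ref_codon_start:min(ref_codon_start + 2L, length(old))], collapse = ""))
        aa_new <- translate_mito(paste(new[ref_codon_start:min(ref_codon_start + 2L, length(new))], collapse = ""))
        cj <- if (aa_old == aa_new) "synonymous"
              else if (aa_new == "*" && aa_old != "*") "truncating"
              else "missense"
      }
      sj <- c(synonymous = 1L, missense = 2L, truncating = 3L)[cj]
      if (sj > sev) { sev <- sj; cons <- cj }
    }
    if (is.na(cons)) {
      feats <- genome$annotations
      hit <- vapply(seq_len(nrow(feats)), function(j)
        pos %in% region_positions(feats$start[j], feats$end[j], L), logical(1))
      f <- feats$feature[hit]
      cons <- if ("tRNA" %in% f) "tRNA" else if ("rRNA" %in% f) "rRNA" else "noncoding"
    }
    consequence[i] <- cons
  }
  variants$consequence <- consequence
  variants$strand_class <- strand_class
  variants$in_dloop <- in_region(variants$position, genome$dloop, L)
  variants$in_origin <- in_region(variants$position, genome$origin_region, L)
  variants
}

#' mtDNA copy number per diploid nuclear genome
#'
#' `2 * coverage_mt / coverage_n`, with nuclear ploidy fixed at two.
#'
#' @param coverage_mt mean mtDNA coverage depth (fold).
#' @param coverage_n mean nuclear coverage depth (fold).
#' @return numeric copy number(s).
#' @examples
#' mtdna_copy_number(6931, 18.48) # ~750
#' @export
mtdna_copy_number <- function(coverage_mt, coverage_n) {
  if (any(coverage_mt <= 0) || any(coverage_n <= 0))
    stop("coverages must be positive")
  coverage_mt / coverage_n * 2
}

#' Read an mt_genome from FASTA plus an annotation table
#'
#' @param fasta path to a single-sequence FASTA file.
#' @param annotation path to a TSV with columns name, start, end, strand,
#'   feature.
#' @inheritParams mt_genome
#' @return an [mt_genome].
#' @export
read_mt_genome <- function(fasta, annotation,
                           dloop = c(16024L, 576L),
                           origin_region = c(16197L, 191L)) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) stop("expected a single-sequence FASTA")
  ann <- read.delim(annotation, stringsAsFactors = FALSE)
  mt_genome(as.character(seqs[[1]]), ann, dloop = dloop,
            origin_region = origin_region)
}

#' Write an mt_genome to FASTA plus an annotation table
#'
#' @param genome an [mt_genome].
#' @param fasta,annotation output paths.
#' @param name sequence name used in the FASTA header.
#' @return invisibly, the two paths.
#' @export
write_mt_genome <- function(genome, fasta, annotation, name = "chrM") {
  s <- Biostrings::DNAStringSet(genome$sequence)
  names(s) <- name
  Biostrings::writeXStringSet(s, fasta, width = 70L)
  write.table(genome$annotations, annotation, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta, annotation))
}
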