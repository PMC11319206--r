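# shared fixtures, built in code

toy_genome <- function(seed = 1L, ...) generate_toy_genome(seed = seed, ...)

# minimal metadata data.frame for hand-built cohorts
make_meta <- function(clone_id, donor_id, tissue = "colon", age = 50,
                      cov_n = 30, cov_mt = 11250, clonality = 0.45) {
  data.frame(clone_id = clone_id, donor_id = donor_id, tissue = tissue,
             donor_age = age, mean_coverage_nuclear = cov_n,
             mean_coverage_mt = cov_mt, nuclear_clonality_vaf = clonality,
             stringsAsFactors = FALSE)
}

# hand-built mt_cohort from a calls data.frame (all measurements called)
make_cohort <- function(meta, calls, phylo = list(), bulk = NULL) {
  if (is.null(calls$called)) calls$called <- rep(TRUE, nrow(calls))
  structure(list(clones = meta, measurements = calls,
                 calls = calls[calls$called, , drop = FALSE],
                 phylo = phylo, bulk = bulk),
            class = "mt_cohort")
}

# reference translation via seqinr (vertebrate mitochondrial code),
# independent of the Biostrings-based implementation path
oracle_translate <- function(dna) {
  paste(seqinr::translate(strsplit(tolower(dna), "")[[1]], numcode = 2),
        collapse = "")
}

# brute-force consequence oracle: mutate the CDS, translate whole protein
oracle_consequence <- function(genome, gene, idx_in_cds, alt_coding_base) {
  ann <- genome$annotations
  row <- ann[ann$name == gene, ]
  p <- if (row$start <= row$end) seq.int(row$start, row$end)
       else c(seq.int(row$start, genome$length), seq.int(1L, row$end))
  bases <- substring(genome$sequence, p, p)
  if (row$strand == "-") {
    p <- rev(p)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    bases <- rev(unname(comp[bases]))
  }
  prot_ref <- oracle_translate(paste(bases, collapse = ""))
  bases[idx_in_cds] <- alt_coding_base
  prot_alt <- oracle_translate(paste(bases, collapse = ""))
  if (prot_alt == prot_ref) return("synonymous")
  stop_ref <- regexpr("\\*", prot_ref)[1]
  stop_alt <- regexpr("\\*", prot_alt)[1]
  if (stop_alt > 0 && (stop_ref < 0 || stop_alt < stop_ref)) "truncating"
  else "missense"
}
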