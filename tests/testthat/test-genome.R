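test_that("toy genome construction is valid and deterministic", {
  g1 <- generate_toy_genome(seed = 4, n_genes = 3, length = 1200)
  g2 <- generate_toy_genome(seed = 4, n_genes = 3, length = 1200)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$annotations, g2$annotations)
  expect_equal(g1$length, 1200)
  cds <- g1$annotations[g1$annotations$feature == "CDS", ]
  expect_gte(nrow(cds), 3)
  for (j in seq_len(nrow(cds))) {
    p <- seq.int(cds$start[j], cds$end[j])
    s <- paste(substring(g1$sequence, p, p), collapse = "")
    if (cds$strand[j] == "-") {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      s <- paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
    }
    prot <- oracle_translate(s)
    expect_match(substr(prot, 1, 1), "M")
    # single terminal stop, none internal
    expect_equal(regexpr("\\*", prot)[1], nchar(prot))
  }
})

test_that("genome round-trips through FASTA + annotation files", {
  g <- generate_toy_genome(seed = 9)
  fa <- tempfile(fileext = ".fa"); an <- tempfile(fileext = ".tsv")
  write_mt_genome(g, fa, an)
  g2 <- read_mt_genome(fa, an, dloop = g$dloop, origin_region = g$origin_region)
  expect_identical(g2$sequence, g$sequence)
  expect_equal(g2$annotations$start, g$annotations$start)
  expect_equal(g2$annotations$feature, g$annotations$feature)
})

test_that("consequence annotation agrees with a brute-force translation oracle", {
  g <- generate_toy_genome(seed = 2, n_genes = 2, length = 600)
  cds <- g$annotations[g$annotations$feature == "CDS", ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (j in seq_len(nrow(cds))) {
    p <- seq.int(cds$start[j], cds$end[j])
    if (cds$strand[j] == "-") p <- rev(p)
    for (idx in seq_along(p)) {
      pos <- p[idx]
      ref <- substring(g$sequence, pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        got <- annotate_variants(
          data.frame(position = pos, ref = ref, alt = alt), g)$consequence
        alt_coding <- if (cds$strand[j] == "-") unname(comp[alt]) else alt
        want <- oracle_consequence(g, cds$name[j], idx, alt_coding)
        expect_equal(got, want,
                     info = paste("gene", cds$name[j], "pos", pos, ref, ">", alt))
      }
    }
  }
})

test_that("strand class follows the mutated pyrimidine; regions flagged", {
  g <- generate_toy_genome(seed = 5)
  s <- strsplit(g$sequence, "")[[1]]
  pos_c <- which(s == "C")[1]
  pos_g <- which(s == "G")[1]
  v <- annotate_variants(
    data.frame(position = c(pos_c, pos_g), ref = c("C", "G"),
               alt = c("T", "A")), g)
  expect_equal(v$strand_class, c("light", "heavy"))
  # wrapped regions: position 1 is inside both control regions of the toy
  expect_true(in_region(1L, g$dloop, g$length))
  expect_true(in_region(1L, g$origin_region, g$length))
  expect_false(in_region(g$length %/% 2L, g$origin_region, g$length))
  # rCRS-style wrap arithmetic
  expect_true(in_region(16300L, c(16197L, 191L), 16569L))
  expect_true(in_region(100L, c(16197L, 191L), 16569L))
  expect_false(in_region(1000L, c(16197L, 191L), 16569L))
})

test_that("frameshift and stop-gain InDel/SNV calls are truncating", {
  g <- generate_toy_genome(seed = 2, n_genes = 2, length = 600)
  cds <- g$annotations[g$annotations$feature == "CDS", ][1, ]
  pos <- cds$start + 4L # inside the CDS, plus strand
  ref <- substring(g$sequence, pos, pos)
  v <- annotate_variants(
    data.frame(position = pos, ref = ref, alt = paste0(ref, "A"),
               variant_type = "insertion"), g)
  expect_equal(v$consequence, "truncating")
  # allele mismatch errors name the position
  bad <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(annotate_variants(
    data.frame(position = pos, ref = bad, alt = ref), g),
    as.character(pos))
})

test_that("copy number is the coverage ratio times ploidy two", {
  expect_equal(mtdna_copy_number(375, 1), 750)
  expect_equal(mtdna_copy_number(100, 100), 2)
  expect_equal(mtdna_copy_number(6931, 18.48), 750.1, tolerance = 1e-4)
  expect_error(mtdna_copy_number(0, 10), "positive")
  # linear in mt coverage, inverse in nuclear coverage
  cm <- runif(20, 100, 10000); cn <- runif(20, 5, 60); a <- runif(20, .5, 3)
  expect_equal(mtdna_copy_number(a * cm, cn), a * mtdna_copy_number(cm, cn))
  expect_equal(mtdna_copy_number(cm, a * cn), mtdna_copy_number(cm, cn) / a)
})
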