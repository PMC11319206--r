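test_that("mutational opportunity matches exhaustive enumeration", {
  g <- generate_toy_genome(seed = 3, n_genes = 1, length = 400)
  opp <- mutation_opportunity(g)
  cds <- g$annotations[g$annotations$feature == "CDS", ]
  cds_len <- sum(cds$end - cds$start + 1L)
  expect_equal(sum(opp$counts), 3L * cds_len) # conservation
  # brute-force oracle over every CDS position x alternative base
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  want <- c(synonymous = 0L, missense = 0L, truncating = 0L)
  for (j in seq_len(nrow(cds))) {
    p <- seq.int(cds$start[j], cds$end[j])
    if (cds$strand[j] == "-") p <- rev(p)
    for (idx in seq_along(p)) {
      ref <- substring(g$sequence, p[idx], p[idx])
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        ac <- if (cds$strand[j] == "-") unname(comp[alt]) else alt
        cc <- oracle_consequence(g, cds$name[j], idx, ac)
        want[cc] <- want[cc] + 1L
      }
    }
  }
  expect_equal(unname(opp$counts[names(want)]), unname(want))
})

test_that("a synonymous germline substitution changes opportunity only locally", {
  g <- generate_toy_genome(seed = 3, n_genes = 1, length = 400)
  opp <- mutation_opportunity(g)
  syn_row <- opp$table[opp$table$consequence == "synonymous", ][1, ]
  opp2 <- mutation_opportunity(
    g, germline = syn_row[, c("position", "ref", "alt")])
  # totals conserved; per-category shifts bounded by one codon's worth
  expect_equal(sum(opp2$counts), sum(opp$counts))
  expect_true(all(abs(opp2$counts - opp$counts) <= 9))
})

test_that("the uniform null dN/dS is centred at one on a toy genome", {
  g <- generate_toy_genome(seed = 12, n_genes = 3, length = 1500)
  # enough mutations per iteration that the count-ratio bias (~1/n_syn)
  # stays small
  null <- simulate_null_dnds(g, n_mut = 150, iterations = 1500)
  m <- mean(null$missense)
  se <- sd(null$missense) / sqrt(length(null$missense))
  expect_lt(abs(m - 1), max(3 * se, 0.1))
  expect_gt(median(null$missense), 0.7)
  expect_lt(median(null$missense), 1.3)
})

test_that("weighted null with uniform weights equals the uniform null", {
  g <- generate_toy_genome(seed = 13, n_genes = 2, length = 800)
  w <- setNames(rep(1, 12),
                as.vector(outer(c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"),
                                c("heavy", "light"), paste, sep = "|")))
  set.seed(21)
  a <- simulate_null_dnds(g, n_mut = 25, iterations = 400)
  set.seed(21)
  b <- simulate_null_dnds(g, n_mut = 25, weights = w, iterations = 400)
  expect_equal(a$missense, b$missense)
  set.seed(33)
  c1 <- simulate_null_dnds(g, n_mut = 25, iterations = 300)
  set.seed(33)
  c2 <- simulate_null_dnds(g, n_mut = 25, iterations = 300)
  expect_identical(c1$missense, c2$missense) # fixed seed -> identical null
})

test_that("per-tissue report flags suppressed truncating expansion", {
  g <- generate_toy_genome(seed = 14, n_genes = 3, length = 1500)
  tab <- mutation_opportunity(g)$table
  syn <- tab[tab$consequence == "synonymous", ]
  tru <- tab[tab$consequence == "truncating", ]
  mis <- tab[tab$consequence == "missense", ]
  meta <- make_meta(sprintf("c%02d", 1:40), "DA")
  # synonymous mutations reach homoplasmy; truncating capped below 0.9
  calls <- rbind(
    data.frame(clone_id = meta$clone_id[1:20],
               syn[1:20, c("position", "ref", "alt")],
               vaf = c(rep(0.95, 12), rep(0.5, 8))),
    data.frame(clone_id = meta$clone_id[21:40],
               tru[1:20, c("position", "ref", "alt")],
               vaf = runif(20, 0.1, 0.85)),
    data.frame(clone_id = meta$clone_id,
               mis[1:40, c("position", "ref", "alt")],
               vaf = runif(40, 0.1, 0.9)))
  classified <- data.frame(position = calls$position, ref = calls$ref,
                           alt = calls$alt, donor_id = "DA",
                           origin_class = "PZ_simple")
  rep_ <- dnds_report(make_cohort(meta, calls), classified, g,
                      iterations = 300)
  t_ <- rep_$tissues$colon
  expect_equal(t_$n_syn, 20)
  expect_equal(t_$n_tru, 20)
  expect_lt(t_$fisher_homoplasmy$p.value, 0.05)
  # empty input produces a structured empty report
  empty <- dnds_report(make_cohort(meta, calls[0, ]), classified[0, ], g)
  expect_s3_class(empty, "mt_dnds")
  expect_length(empty$tissues, 0)
})
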