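test_that("ML rate and binomial tail match closed forms and a summation oracle", {
  # zero background: p_hat 0, any sharing is deterministic evidence
  m0 <- ml_rate_and_tail(0, 500, 3, 20)
  expect_equal(m0$p_hat_ml, 0)
  expect_equal(m0$tail_p, 0)
  # independent summation oracle
  m1 <- ml_rate_and_tail(10, 100, 1, 10)
  oracle <- sum(vapply(1:10, function(x)
    choose(10, x) * 0.1^x * 0.9^(10 - x), numeric(1)))
  expect_equal(m1$p_hat_ml, 0.1)
  expect_equal(m1$tail_p, oracle, tolerance = 1e-12)
  expect_equal(m1$tail_p, 0.651, tolerance = 1e-3)
  # published Het_FE case: sharing far beyond chance
  m2 <- ml_rate_and_tail(2, 2069, 14, 27)
  expect_lt(m2$tail_p, 1e-10)
  expect_error(ml_rate_and_tail(1, 10, 0, 10), "x_obs")
})

test_that("binomial tail matches a Monte-Carlo estimate", {
  set.seed(99)
  m <- ml_rate_and_tail(15, 150, 3, 25)
  draws <- rbinom(1e5, 25, m$p_hat_ml)
  mc <- mean(draws >= 3)
  se <- sqrt(mc * (1 - mc) / 1e5)
  expect_lt(abs(m$tail_p - mc), 3 * se)
})

# hand-built cohort: 3 donors x 6 clones
hand_cohort <- function(calls, phylo = list(), bulk = NULL) {
  meta <- make_meta(sprintf("D%d_c%d", rep(1:3, each = 6), rep(1:6, 3)),
                    rep(c("D1", "D2", "D3"), each = 6),
                    tissue = rep(c("colon", "colon", "fibroblast"), each = 6),
                    age = rep(c(40, 70, 55), each = 6))
  make_cohort(meta, calls, phylo = phylo, bulk = bulk)
}

test_that("origin classification follows the rule precedence", {
  calls <- rbind(
    # exclusive sharing in D1 -> Het_FE
    data.frame(clone_id = c("D1_c1", "D1_c2", "D1_c3"), position = 101L,
               ref = "A", alt = "G", vaf = 0.4),
    # >= 2 clones in each of 2 donors -> PZ_recurrent
    data.frame(clone_id = c("D1_c1", "D1_c2", "D2_c1", "D2_c2"),
               position = 202L, ref = "C", alt = "T", vaf = 0.1),
    # singleton without bulk support -> PZ_simple
    data.frame(clone_id = "D3_c5", position = 303L, ref = "G", alt = "A",
               vaf = 0.8),
    # singleton with matched bulk support -> Het_FE
    data.frame(clone_id = "D3_c6", position = 404L, ref = "T", alt = "C",
               vaf = 0.02))
  bulk <- data.frame(donor_id = "D3", tissue = "blood", position = 404L,
                     ref = "T", alt = "C", vaf = 0.02)
  co <- hand_cohort(calls, bulk = bulk)
  cl <- classify_variants(co)
  got <- setNames(cl$origin_class, paste(cl$position, cl$donor_id))
  expect_equal(unname(got["101 D1"]), "Het_FE")
  expect_equal(unname(got["202 D1"]), "PZ_recurrent")
  expect_equal(unname(got["202 D2"]), "PZ_recurrent")
  expect_equal(unname(got["303 D3"]), "PZ_simple")
  expect_equal(unname(got["404 D3"]), "Het_FE")
  expect_equal(cl$rule_fired[cl$position == 404L], "matched_bulk")
  # every observation receives exactly one class
  expect_false(any(is.na(cl$origin_class)))
  expect_equal(nrow(cl), nrow(unique(cl[, c("position", "donor_id")])))
})

test_that("sharing with sporadic background uses the binomial tail", {
  # D1 shares the variant in 4/6 clones; one sporadic carrier elsewhere
  calls <- rbind(
    data.frame(clone_id = paste0("D1_c", 1:4), position = 550L, ref = "A",
               alt = "C", vaf = 0.3),
    data.frame(clone_id = "D2_c3", position = 550L, ref = "A", alt = "C",
               vaf = 0.02))
  co <- hand_cohort(calls)
  cl <- classify_variants(co)
  d1 <- cl[cl$donor_id == "D1", ]
  # p_hat = 1/12, tail P(X >= 4 | n = 6) is well below 0.01
  expect_equal(d1$origin_class, "Het_FE")
  expect_equal(d1$rule_fired, "binomial_tail")
  expect_lt(d1$tail_p, 0.01)
  # weak sharing (2/6) against a sporadic background goes postzygotic
  calls2 <- rbind(
    data.frame(clone_id = paste0("D1_c", 1:2), position = 660L, ref = "G",
               alt = "T", vaf = 0.1),
    data.frame(clone_id = "D2_c1", position = 660L, ref = "G",
               alt = "T", vaf = 0.05))
  cl2 <- classify_variants(hand_cohort(calls2))
  d1b <- cl2[cl2$donor_id == "D1", ]
  expect_equal(d1b$origin_class, "PZ_simple")
  expect_gt(d1b$tail_p, 0.01)
})

test_that("late-branched exclusive sharing is postzygotic", {
  # D1 tree: (c1,c2) form a cherry whose ancestor carries > 100 mutations
  tr <- ape::read.tree(text = paste0(
    "(((D1_c1:500,D1_c2:500):150,D1_c3:650):5,",
    "(D1_c4:600,(D1_c5:400,D1_c6:400):200):5);"))
  calls <- data.frame(clone_id = c("D1_c1", "D1_c2"), position = 777L,
                      ref = "C", alt = "A", vaf = 0.5)
  co <- hand_cohort(calls, phylo = list(D1 = tr))
  cl <- classify_variants(co)
  expect_equal(cl$origin_class, "PZ_simple")
  expect_equal(cl$rule_fired, "late_branch")
  # same sharing with an early MRCA stays Het_FE
  tr2 <- tr
  tr2$edge.length[tr2$edge.length == 150] <- 10
  cl2 <- classify_variants(hand_cohort(calls, phylo = list(D1 = tr2)))
  expect_equal(cl2$origin_class, "Het_FE")
})

test_that("tissue-recurrent hotspots require age signal and recurrence", {
  meta <- make_meta(sprintf("D%d_c%d", rep(1:6, each = 3), rep(1:3, 6)),
                    rep(paste0("D", 1:6), each = 3), tissue = "colon",
                    age = rep(c(85, 80, 75, 30, 25, 20), each = 3))
  # hotspot carried by the three old donors only
  calls <- data.frame(clone_id = c("D1_c1", "D1_c2", "D2_c1", "D2_c2",
                                   "D3_c1", "D3_c2"),
                      position = 414L, ref = "T", alt = "G", vaf = 0.2)
  co <- make_cohort(meta, calls)
  cl <- classify_variants(co)
  fl <- detect_tissue_recurrent(cl, co)
  expect_true(414L %in% fl$position)
  # uniform ages: no flag
  meta2 <- meta; meta2$donor_age <- 50
  fl2 <- detect_tissue_recurrent(classify_variants(make_cohort(meta2, calls)),
                                 make_cohort(meta2, calls))
  expect_false(414L %in% fl2$position)
  # single-donor recurrence: no flag
  calls3 <- calls[calls$clone_id %in% c("D1_c1", "D1_c2"), ]
  co3 <- make_cohort(meta, calls3)
  fl3 <- detect_tissue_recurrent(classify_variants(co3), co3)
  expect_equal(nrow(fl3), 0)
})
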