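# distribution equality helper: chi-squared homogeneity on pooled bins
chisq_homogeneity <- function(a, b) {
  lv <- sort(unique(c(a, b)))
  ta <- table(factor(a, levels = lv))
  tb <- table(factor(b, levels = lv))
  keep <- (ta + tb) >= 5
  tab <- rbind(ta[keep], tb[keep])
  suppressWarnings(chisq.test(tab)$p.value)
}

test_that("absorbing states persist in both models", {
  for (model in c("mitotic", "homeostatic")) {
    s0 <- simulate_drift(drift_config(n = 40, p0 = 0, g_max = 50,
                                      n_cells = 64, model = model), seed = 1)
    s1 <- simulate_drift(drift_config(n = 40, p0 = 1, g_max = 50,
                                      n_cells = 64, model = model), seed = 1)
    expect_true(all(s0$freq_final == 0))
    expect_true(all(s1$freq_final == 1))
  }
})

test_that("mitotic one-step distribution matches the molecule-by-molecule oracle", {
  set.seed(7)
  n <- 10L; k <- 5L; reps <- 20000L
  fast <- mtmosaic:::cpp_drift_two_allele(rep.int(k, reps), n, 1L, 0L,
                                          integer(0), n)$k_final
  slow <- vapply(seq_len(reps %/% 4), function(i)
    drift_step_oracle(c(k, n - k), "mitotic")[1], integer(1))
  p <- chisq_homogeneity(fast[seq_along(slow)], slow)
  expect_gt(p, 0.01)
})

test_that("homeostatic acceleration matches the naive Moran event simulator", {
  set.seed(8)
  n <- 12L; k <- 5L; reps <- 20000L
  fast <- mtmosaic:::cpp_drift_two_allele(rep.int(k, reps), n, 1L, 1L,
                                          integer(0), n)$k_final
  naive <- mtmosaic:::cpp_moran_events_naive(k, n, n, reps)
  expect_gt(chisq_homogeneity(fast, naive), 0.01)
  # and against the pure-R molecule oracle at smaller scale
  slow <- vapply(seq_len(4000), function(i)
    drift_step_oracle(c(k, n - k), "homeostatic")[1], integer(1))
  expect_gt(chisq_homogeneity(fast[seq_along(slow)], slow), 0.01)
})

test_that("single Moran event transition probabilities match the closed form", {
  set.seed(9)
  n <- 10L; k <- 3L; reps <- 50000L
  ev <- mtmosaic:::cpp_moran_events_naive(k, n, 1L, reps)
  p_theory <- k * (n - k) / (n * (n - 1)) # same for up and down moves
  p_up <- mean(ev == k + 1); p_dn <- mean(ev == k - 1)
  se <- sqrt(p_theory * (1 - p_theory) / reps)
  expect_lt(abs(p_up - p_theory), 4 * se)
  expect_lt(abs(p_dn - p_theory), 4 * se)
  expect_equal(sort(unique(ev)), c(k - 1, k, k + 1))
})

test_that("frequency is a martingale and variance grows twice as fast homeostatically", {
  set.seed(10)
  n <- 100L; k0 <- 30L; cells <- 40000L
  m <- mtmosaic:::cpp_drift_two_allele(rep.int(k0, cells), n, 10L, 0L,
                                       integer(0), n)$k_final / n
  h <- mtmosaic:::cpp_drift_two_allele(rep.int(k0, cells), n, 10L, 1L,
                                       integer(0), n)$k_final / n
  for (fr in list(m, h)) {
    se <- sd(fr) / sqrt(cells)
    expect_lt(abs(mean(fr) - 0.3), 3 * se)
  }
  expect_equal(var(h) / var(m), 2, tolerance = 0.15)
})

test_that("fixation probability converges to the initial frequency", {
  set.seed(12)
  s <- simulate_drift(drift_config(n = 30, p0 = 0.3, g_max = 2000,
                                   n_cells = 6000), seed = 12)
  fixed <- mean(s$freq_final == 1)
  lost <- mean(s$freq_final == 0)
  expect_equal(fixed + lost, 1) # fully absorbed at this horizon
  se <- sqrt(0.3 * 0.7 / 6000)
  expect_lt(abs(fixed - 0.3), 3.5 * se)
})

test_that("fixed seeds give bit-identical simulations", {
  cfg <- drift_config(n = 80, p0 = 0.2, g_max = 60, n_cells = 200)
  a <- simulate_drift(cfg, record_at = c(0, 30, 60), seed = 77)
  b <- simulate_drift(cfg, record_at = c(0, 30, 60), seed = 77)
  expect_identical(a$freq, b$freq)
  expect_identical(a$fix_time, b$fix_time)
  ms1 <- simulate_mutation_accumulation(n = 60, n_cells = 50, g = 40,
                                        r = 2e-6, seed = 5)
  ms2 <- simulate_mutation_accumulation(n = 60, n_cells = 50, g = 40,
                                        r = 2e-6, seed = 5)
  expect_identical(ms1$mut_freqs, ms2$mut_freqs)
})

test_that("turnovers to fixation decrease with initial frequency", {
  tf <- turnovers_to_fixation(n = 40, p0 = c(0.1, 0.5, 0.9),
                              n_cells = 2500, g_max = 3000, seed = 14)
  expect_true(all(diff(tf$mean_fix_turnovers) < 0))
  expect_true(all(diff(tf$fixing_frac) > 0))
  # small-n mean fixation time against the molecule-by-molecule oracle
  set.seed(15)
  n <- 12L; reps <- 400L
  oracle_times <- rep(NA_real_, reps)
  for (i in seq_len(reps)) {
    counts <- c(6L, 6L)
    for (t in 1:500) {
      counts <- drift_step_oracle(counts, "mitotic")
      if (counts[1] == n) { oracle_times[i] <- t; break }
      if (counts[1] == 0L) break
    }
  }
  ot <- oracle_times[!is.na(oracle_times)]
  tf2 <- turnovers_to_fixation(n = n, p0 = 0.5, n_cells = 4000,
                               g_max = 500, seed = 16)
  se <- sd(ot) / sqrt(length(ot))
  expect_lt(abs(tf2$mean_fix_turnovers - mean(ot)), 3.5 * se)
})

test_that("heterozygosity decays geometrically, faster homeostatically", {
  set.seed(17)
  n <- 60L; cells <- 8000L
  het_at <- function(model, g) {
    r <- mtmosaic:::cpp_drift_two_allele(rep.int(30L, cells), n, g,
                                         if (model == "mitotic") 0L else 1L,
                                         integer(0), n)$k_final / n
    mean(r * (1 - r))
  }
  hm <- vapply(c(15L, 30L, 45L), function(g) het_at("mitotic", g), numeric(1))
  hh <- vapply(c(15L, 30L, 45L), function(g) het_at("homeostatic", g),
               numeric(1))
  # log-linear decay: successive log ratios roughly equal
  lr <- diff(log(hm))
  expect_equal(lr[1], lr[2], tolerance = 0.12)
  expect_true(all(hh < hm))
})
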