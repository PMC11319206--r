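clean_support <- function(position = 8000L, variant_type = "SNV") {
  data.frame(position = position, variant_type = variant_type,
             mean_mapq = 60, mean_baseq = 30, mean_position_fraction = 0.5,
             forward_fraction = 0.5, max_mismatches = 2, pairing_ok = TRUE,
             frac_additional_indels = ifelse(
               variant_type == "SNV", NA, 0.1),
             stringsAsFactors = FALSE)
}

test_that("clean support passes; each criterion fires its reason code", {
  v <- apply_read_filters(clean_support())
  expect_true(v$pass)
  expect_equal(v$reasons, "")

  cases <- list(
    list(col = "mean_mapq", val = 20, code = "mapq"),
    list(col = "mean_baseq", val = 10, code = "baseq"),
    list(col = "mean_position_fraction", val = 0.9, code = "position"),
    list(col = "forward_fraction", val = 0.05, code = "strand"),
    list(col = "max_mismatches", val = 7, code = "mismatches"),
    list(col = "pairing_ok", val = FALSE, code = "pairing"))
  for (cs in cases) {
    s <- clean_support()
    s[[cs$col]] <- cs$val
    v <- apply_read_filters(s)
    expect_false(v$pass)
    expect_equal(v$reasons, cs$code)
  }
})

test_that("boundary values follow the strict printed inequalities", {
  s <- clean_support()
  s$mean_mapq <- 25; s$mean_baseq <- 15
  s$mean_position_fraction <- 0.15; s$forward_fraction <- 0.10
  s$max_mismatches <- 4
  expect_true(apply_read_filters(s)$pass)
  s$mean_position_fraction <- 0.85; s$forward_fraction <- 0.90
  expect_true(apply_read_filters(s)$pass)
  s$max_mismatches <- 5
  expect_false(apply_read_filters(s)$pass)
})

test_that("positional blacklists and InDel rules fire", {
  expect_equal(apply_read_filters(clean_support(position = 310L))$reasons,
               "blacklist")
  expect_equal(apply_read_filters(clean_support(position = 16185L))$reasons,
               "blacklist")
  v <- apply_read_filters(clean_support(position = 5894L,
                                        variant_type = "insertion"))
  expect_equal(v$reasons, "indel_locus")
  s <- clean_support(variant_type = "deletion")
  s$frac_additional_indels <- 0.6
  expect_equal(apply_read_filters(s)$reasons, "indel_noise")
  # SNVs are exempt from the InDel-only locus rule
  expect_true(apply_read_filters(clean_support(position = 5894L))$pass)
  s2 <- clean_support(variant_type = "insertion")
  s2$frac_additional_indels <- NULL
  expect_error(apply_read_filters(s2), "frac_additional_indels")
})

test_that("filter verdict is monotone in every summary field", {
  set.seed(81)
  # worsening = lower quality scores, fractions further from 1/2, more
  # mismatches, broken pairing
  away_from_half <- function(x) 0.5 + (x - 0.5) * runif(1, 1, 3)
  worsen <- list(
    mean_mapq = function(x) x - runif(1, 0, 30),
    mean_baseq = function(x) x - runif(1, 0, 20),
    mean_position_fraction = away_from_half,
    forward_fraction = away_from_half,
    max_mismatches = function(x) x + sample(1:5, 1),
    pairing_ok = function(x) FALSE)
  for (i in 1:60) {
    s <- clean_support()
    s$mean_mapq <- runif(1, 10, 60)
    s$mean_baseq <- runif(1, 5, 40)
    s$mean_position_fraction <- runif(1, 0.05, 0.95)
    s$forward_fraction <- runif(1, 0.05, 0.95)
    s$max_mismatches <- sample(0:7, 1)
    base_fail <- !apply_read_filters(s)$pass
    f <- sample(names(worsen), 1)
    s2 <- s
    s2[[f]] <- worsen[[f]](s[[f]])
    if (base_fail) expect_false(apply_read_filters(s2)$pass)
  }
})

test_that("planned QC violations are recovered exactly", {
  plan <- data.frame(
    position = c(514L, 8000L, 8000L, 955L, 9000L),
    variant_type = c("SNV", "SNV", "SNV", "insertion", "deletion"),
    violations = c("blacklist", "mapq;strand", "", "indel_locus;baseq",
                   "indel_noise"),
    stringsAsFactors = FALSE)
  sup <- generate_read_support(plan, seed = 3)
  v <- apply_read_filters(sup)
  got <- lapply(strsplit(v$reasons, ";"), sort)
  want <- lapply(strsplit(plan$violations, ";"), sort)
  expect_equal(got, want)
  expect_equal(v$pass, !nzchar(plan$violations))
  # contradictory plans error
  bad <- data.frame(position = 8000L, variant_type = "SNV",
                    violations = "blacklist")
  expect_error(generate_read_support(bad), "inconsistent")
  bad2 <- data.frame(position = 310L, variant_type = "SNV", violations = "")
  expect_error(generate_read_support(bad2), "inconsistent")
})
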