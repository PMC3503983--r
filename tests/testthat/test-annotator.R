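test_that("an exact planted LTR pair is recovered to the base", {
  cfg <- sim_config(region_length = 3e4, seed = 11,
                    elements = list(plant_spec(family = "RLX01",
                                               age_years = 0)))
  reg <- simulate_region(cfg)
  tr <- reg$truth
  l5 <- tr[tr$role %in% "five_prime_LTR", ]
  l3 <- tr[tr$role %in% "three_prime_LTR", ]
  pairs <- find_ltr_pairs(reg$sequence)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$left_start, l5$start)
  expect_equal(pairs$left_end, l5$end)
  expect_equal(pairs$right_start, l3$start)
  expect_equal(pairs$right_end, l3$end)
  expect_equal(pairs$identity, 1)
})

test_that("a diverged planted pair is recovered with plausible identity", {
  cfg <- sim_config(region_length = 3e4, seed = 12,
                    elements = list(plant_spec(family = "RLX02",
                                               age_years = 2e6)))
  reg <- simulate_region(cfg)
  pairs <- find_ltr_pairs(reg$sequence)
  expect_equal(nrow(pairs), 1)
  expect_gte(pairs$identity, 0.90)
  expect_lte(pairs$identity, 0.99)
})

test_that("null background yields no pairs and no library hits", {
  bg <- make_background(1e5, 0.43, 99)
  expect_equal(nrow(find_ltr_pairs(bg)), 0)
  lib <- make_repeat_library(seed = 99)
  expect_equal(nrow(match_library(bg, lib)), 0)
})

test_that("pair search validates its bounds and degenerate input", {
  expect_equal(nrow(find_ltr_pairs("")), 0)
  bg <- make_background(1e4, 0.5, 1)
  expect_error(find_ltr_pairs(bg, min_ltr = 10, seed_k = 20), "seed_k")
  expect_error(find_ltr_pairs(bg, min_span = 150, min_ltr = 100), "min_span")
  expect_error(find_ltr_pairs(bg, min_identity = 0), "bounds")
})

test_that("library matching recovers solo and truncated remnants with coverage", {
  cfg <- sim_config(region_length = 4e4, seed = 14,
                    elements = list(
                      plant_spec(family = "RLX01", age_years = 1e6,
                                 fate = "SoloWithTSD"),
                      plant_spec(family = "RLX02", age_years = 1e6,
                                 fate = "TruncatedSolo",
                                 trunc_fraction = 0.4)))
  reg <- simulate_region(cfg)
  hits <- match_library(reg$sequence, reg$library)
  solo <- hits[hits$family == "RLX01" & hits$role == "LTR", ]
  expect_equal(nrow(solo), 1)
  expect_gte(solo$coverage, 0.95)
  trunc <- hits[hits$family == "RLX02" & hits$role == "LTR", ]
  expect_equal(nrow(trunc), 1)
  expect_lt(abs(trunc$coverage - 0.4), 0.05)
})

test_that("library matching finds reverse-strand copies", {
  lib <- make_repeat_library(n_ltr_families = 1, seed = 21)
  bg <- make_background(2e4, 0.43, 22)
  rc <- seq_rc(lib$sequence[lib$role == "LTR"])
  seqs <- paste0(substr(bg, 1, 1e4), rc, substr(bg, 1e4 + 1, 2e4))
  hits <- match_library(seqs, lib)
  ltr <- hits[hits$role == "LTR", ]
  expect_equal(nrow(ltr), 1)
  expect_equal(ltr$strand, "-")
  expect_equal(ltr$start, 1e4 + 1)
  expect_equal(ltr$coverage, 1)
})

test_that("detect_tsd finds planted duplications and honours its bounds", {
  bg <- make_background(2e3, 0.43, 31)
  tsd <- "ACGTA"
  # boundary-adjacent characters are forced distinct so the planted 5-mer
  # cannot extend to a longer chance duplication
  left <- paste0(substr(bg, 1, 498), "AC")
  core <- paste0("GG", substr(bg, 501, 796), "TT")
  right <- paste0("CA", substr(bg, 801, 1998))
  s <- paste0(left, tsd, core, tsd, right)
  el_start <- 506; el_end <- 505 + nchar(core)
  got <- detect_tsd(s, el_start, el_end, min_len = 4, max_len = 20,
                    window = 2)
  expect_false(is.null(got))
  expect_identical(got$sequence, tsd)
  expect_equal(got$length, 5)
  expect_error(detect_tsd(s, 2, 100), "flank")
})

test_that("detect_tsd equals the brute-force oracle on random flank pairs", {
  set.seed(77)
  for (rep in 1:40) {
    flank <- chars_seq(random_dna_chars(200, 0.43))
    core <- chars_seq(random_dna_chars(150, 0.43))
    tl <- sample(4:12, 1)
    tsd <- chars_seq(random_dna_chars(tl, 0.43))
    seqs <- paste0(flank, tsd, core, tsd, flank)
    s <- 200 + tl + 1
    e <- 200 + tl + 150
    got <- detect_tsd(seqs, s, e, 4, 20, 2)
    ora <- oracle_tsd(seqs, s, e, 4, 20, 2)
    expect_false(is.null(got))
    expect_identical(got$sequence,
                     substr(seqs, ora$ls, ora$le))
    expect_equal(got$length, ora$len)
    expect_equal(got$left_start, ora$ls)
    expect_equal(got$right_start, ora$rs)
    # randomized flanks: implementation and oracle agree on the null, too
    nullseq <- paste0(chars_seq(random_dna_chars(100, 0.43)), core,
                      chars_seq(random_dna_chars(100, 0.43)))
    g0 <- detect_tsd(nullseq, 101, 100 + 150, 4, 20, 2)
    o0 <- oracle_tsd(nullseq, 101, 100 + 150, 4, 20, 2)
    expect_equal(is.null(g0), is.null(o0))
    if (!is.null(g0)) expect_equal(g0$length, o0$len)
  }
})

test_that("assembly builds structural elements, solos, and nested pairs", {
  cfg <- sim_config(region_length = 5e4, seed = 16,
                    elements = list(
                      plant_spec(family = "RLX01", age_years = 1e6),
                      plant_spec(family = "RLX03", age_years = 1e6,
                                 fate = "SoloWithTSD")))
  reg <- simulate_region(cfg)
  el <- annotate_region(reg$sequence, reg$library)
  df <- as.data.frame(el)
  expect_equal(nrow(df), 2)
  intact <- el[[which(df$family == "RLX01")]]
  expect_setequal(intact$sub_features$role,
                  c("five_prime_LTR", "internal", "three_prime_LTR"))
  solo <- el[[which(df$family == "RLX03")]]
  expect_equal(nrow(solo$sub_features), 1)
  expect_equal(solo$sub_features$role, "LTR")
  expect_true(all(df$start >= 1 & df$end <= reg$length))

  nest_cfg <- sim_config(region_length = 5e4, seed = 13,
                         elements = list(
                           plant_spec(family = "RLX01", age_years = 2e6),
                           plant_spec(family = "RLX02", age_years = 5e5,
                                      nest_in = "E001")))
  nreg <- simulate_region(nest_cfg)
  ndf <- as.data.frame(annotate_region(nreg$sequence, nreg$library))
  expect_equal(nrow(ndf), 2)
  guest <- ndf[which.min(ndf$end - ndf$start), ]
  host <- ndf[which.max(ndf$end - ndf$start), ]
  expect_true(guest$start > host$start && guest$end < host$end)
})
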