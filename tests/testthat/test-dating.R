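test_that("LTR alignment behaves on trivial pairs and matches the DP oracle", {
  a <- make_background(100, 0.5, 1)
  aln <- align_ltr_pair(a, a)
  expect_identical(aln$a, aln$b)
  expect_equal(nchar(aln$a), 100)
  expect_equal(aln$score, 100)
  b <- a
  substr(b, 50, 50) <- if (substr(a, 50, 50) == "A") "G" else "A"
  aln2 <- align_ltr_pair(a, b)
  expect_equal(nchar(aln2$a), 100)
  expect_equal(sum(seq_chars(aln2$a) != seq_chars(aln2$b)), 1)
  expect_error(align_ltr_pair("", "ACGT"), "non-empty")

  set.seed(8)
  for (rep in 1:5) {
    x <- chars_seq(random_dna_chars(sample(80:300, 1), 0.5))
    y <- chars_seq(evolve_k2p(seq_chars(x), 2e6, 1.3e-8, 2))
    if (rep > 2) { # introduce an indel so gaps genuinely occur
      cut <- sample(20:40, 1)
      y <- paste0(substr(y, 1, 30), substr(y, 30 + cut + 1, nchar(y)))
    }
    got <- align_ltr_pair(x, y)
    expect_equal(got$score, oracle_align_score(x, y))
  }
})

test_that("K2P distance matches an independent evaluation of the closed form", {
  # P = 0.1, Q = 0.05 constructed exactly on 1000 sites
  a <- strrep("A", 1000)
  b <- paste0(strrep("G", 100), strrep("C", 50), strrep("A", 850))
  est <- k2p_distance(list(a = a, b = b))
  expect_equal(est$P, 0.1)
  expect_equal(est$Q, 0.05)
  K_oracle <- -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05)
  expect_equal(est$K, K_oracle, tolerance = 1e-12)
  expect_equal(est$sites_used, 1000)
  # identical sequences
  z <- k2p_distance(list(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(z$K, 0)
  # saturation
  sat_a <- strrep("A", 100)
  sat_b <- paste0(strrep("G", 50), strrep("C", 10), strrep("A", 40))
  expect_error(k2p_distance(list(a = sat_a, b = sat_b)), "saturation")
  # gap and N columns are excluded
  g <- k2p_distance(list(a = "AC-GTN", b = "ACCGTA"))
  expect_equal(g$sites_used, 4)
})

test_that("K2P distance agrees with the phylogenetics oracle", {
  skip_if_not_installed("ape")
  set.seed(5)
  x <- chars_seq(random_dna_chars(2000, 0.45))
  y <- chars_seq(evolve_k2p(seq_chars(x), 4e6, 1.3e-8, 2))
  est <- k2p_distance(list(a = x, b = y))
  m <- rbind(strsplit(tolower(x), "")[[1]], strsplit(tolower(y), "")[[1]])
  rownames(m) <- c("a", "b")
  K_ape <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))
  expect_equal(est$K, K_ape, tolerance = 1e-9)
})

test_that("K is monotone in P and Q and linear in the small-divergence limit", {
  for (Q in c(0.01, 0.05, 0.1)) {
    Ps <- seq(0, 0.3, by = 0.02)
    Ks <- -0.5 * log(1 - 2 * Ps - Q) - 0.25 * log(1 - 2 * Q)
    expect_true(all(diff(Ks) > 0))
  }
  for (P in c(0.01, 0.05, 0.1)) {
    Qs <- seq(0, 0.2, by = 0.02)
    Ks <- -0.5 * log(1 - 2 * P - Qs) - 0.25 * log(1 - 2 * Qs)
    expect_true(all(diff(Ks) > 0))
  }
  for (split in list(c(0.006, 0.003), c(0.002, 0.001), c(0.004, 0.004))) {
    P <- split[1]; Q <- split[2]
    K <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    expect_lt(abs(K - (P + Q)), 0.01 * (P + Q))
  }
})

test_that("insertion time is K/2r with the standard default rate", {
  expect_equal(insertion_time(0), 0)
  expect_equal(insertion_time(0.026, 1.3e-8), 1.0e6)
  expect_equal(formals(insertion_time)$r, 1.3e-8)
  expect_error(insertion_time(0.1, 0), "r must be")
  expect_error(insertion_time(-0.1), "K must be")
})

test_that("dating a simulated cohort recovers the planted age", {
  cfg <- sim_config(region_length = 1.5e5, seed = 61,
                    elements = lapply(1:20, function(i)
                      plant_spec(age_years = 1e6, fate = "IntactLTR")))
  reg <- simulate_region(cfg)
  dt <- date_elements(reg$truth, reg$sequence, r = 1.3e-8)
  expect_equal(nrow(dt), 20)
  expect_lt(abs(mean(dt$T) / 1e6 - 1), 0.1)
  expect_true(all(dt$sites_used == 1000))
})
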