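test_that("background generation is deterministic, GC-calibrated, and rejects bad input", {
  a <- make_background(1000, 0.5, 42)
  b <- make_background(1000, 0.5, 42)
  expect_identical(a, b)
  expect_equal(nchar(a), 1000)
  big <- make_background(1e5, 0.43, 7)
  expect_lt(abs(gc_content(big) - 0.43), 0.02)
  expect_error(make_background(0, 0.5, 1), "positive")
  expect_false(identical(make_background(1000, 0.5, 42),
                         make_background(1000, 0.5, 43)))
})

test_that("K2P mutation process is calibrated against the closed form", {
  r <- 1.3e-8; kappa <- 2; age <- 1e6; L <- 1000
  exp_div <- expected_ltr_divergence(age, r, kappa)
  expect_gt(exp_div, 0.025)
  expect_lt(exp_div, 0.026)
  # divergence calibration over 50 planted intact elements at fixed age
  cfg <- sim_config(region_length = 2e5, seed = 5,
                    elements = lapply(1:50, function(i)
                      plant_spec(age_years = age, fate = "IntactLTR")))
  reg <- simulate_region(cfg)
  parts <- reg$truth[reg$truth$kind == "part" &
                       reg$truth$role %in% c("five_prime_LTR",
                                             "three_prime_LTR"), ]
  divs <- vapply(unique(parts$parent), function(id) {
    p <- parts[parts$parent == id, ]
    a <- seq_chars(substr(reg$sequence, p$start[1], p$end[1]))
    b <- seq_chars(substr(reg$sequence, p$start[2], p$end[2]))
    mean(a != b)
  }, numeric(1))
  se <- sqrt(exp_div * (1 - exp_div) / L) / sqrt(length(divs))
  expect_lt(abs(mean(divs) - exp_div), 3 * se)
})

test_that("planted fate geometry matches each fate's definition", {
  cfg0 <- sim_config(seed = 3)
  bg <- make_background(3e4, 0.43, 9)
  # age 0: the two LTR copies are identical strings
  pe <- plant_element(bg, plant_spec(family = "RLX01", age_years = 0,
                                     fate = "IntactLTR", position = 5000),
                      cfg0)
  parts <- pe$truth[pe$truth$kind == "part", ]
  l5 <- parts[parts$role == "five_prime_LTR", ]
  l3 <- parts[parts$role == "three_prime_LTR", ]
  expect_identical(substr(pe$sequence, l5$start, l5$end),
                   substr(pe$sequence, l3$start, l3$end))
  el <- pe$truth[pe$truth$kind == "ltr_element", ]
  # TSD copies flank the element
  expect_identical(substr(pe$sequence, el$start - 5, el$start - 1),
                   substr(pe$sequence, el$end + 1, el$end + 5))
  expect_identical(substr(pe$sequence, el$start - 5, el$start - 1),
                   el$evidence)

  # solo with TSD: one LTR-length feature with identical flanking 5-mers
  ps <- plant_element(bg, plant_spec(family = "RLX02", age_years = 1e6,
                                     fate = "SoloWithTSD", tsd_length = 5,
                                     position = 5000), cfg0)
  es <- ps$truth[ps$truth$kind == "ltr_element", ]
  expect_equal(es$end - es$start + 1, 1000)
  expect_identical(substr(ps$sequence, es$start - 5, es$start - 1),
                   substr(ps$sequence, es$end + 1, es$end + 5))

  # truncated solo keeps the configured LTR fraction
  pt <- plant_element(bg, plant_spec(family = "RLX03", age_years = 1e6,
                                     fate = "TruncatedSolo",
                                     trunc_fraction = 0.4, position = 5000),
                      cfg0)
  et <- pt$truth[pt$truth$kind == "ltr_element", ]
  expect_equal(et$end - et$start + 1, 400)

  # LTR-deleted fates retain the named parts only
  for (fate in c("ThreePrimeLTRDeleted", "FivePrimeLTRDeleted")) {
    pd <- plant_element(bg, plant_spec(family = "RLX04", age_years = 1e6,
                                       fate = fate, position = 5000), cfg0)
    roles <- pd$truth$role[pd$truth$kind == "part"]
    missing <- if (fate == "ThreePrimeLTRDeleted") "three_prime_LTR"
               else "five_prime_LTR"
    expect_false(missing %in% roles)
    expect_true("internal" %in% roles)
  }

  # recombination complex joins parts of two families
  pr <- plant_element(bg, plant_spec(family = "RLX05", age_years = 1e6,
                                     fate = "RecombinationComplex",
                                     position = 5000), cfg0)
  pfam <- unique(pr$truth$family[pr$truth$kind == "part"])
  expect_length(pfam, 2)
})

test_that("fate-incompatible specs are rejected", {
  expect_error(plant_spec(fate = "SoloWithTSD", tsd_length = 0), "tsd_length")
  expect_error(plant_spec(age_years = -1), "age_years")
  expect_error(sim_config(region_length = 500), "10 kb")
  cfg <- sim_config(region_length = 2e4, seed = 1,
                    elements = list(plant_spec(nest_in = "NOPE")))
  expect_error(simulate_region(cfg), "nest_in")
})

test_that("region simulation is deterministic and nesting is consistent", {
  cfg <- sim_config(region_length = 5e4, seed = 13,
                    elements = list(
                      plant_spec(family = "RLX01", age_years = 2e6),
                      plant_spec(family = "RLX02", age_years = 5e5,
                                 nest_in = "E001")))
  r1 <- simulate_region(cfg)
  r2 <- simulate_region(cfg)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$truth, r2$truth)
  tr <- r1$truth[r1$truth$kind == "ltr_element", ]
  host <- tr[tr$feature_id == "E001", ]
  guest <- tr[tr$feature_id == "E002", ]
  expect_identical(guest$parent, "E001")
  expect_true(guest$start > host$start && guest$end < host$end)
  expect_true(all(r1$truth$start >= 1 & r1$truth$end <= r1$length))
})

test_that("truth emission round-trips exactly and conserves feature counts", {
  reg <- fate_region(seed = 2, n_elements = 5)
  dir <- withr::local_tempdir()
  paths <- emit_truth(reg, dir)
  expect_true(all(file.exists(paths)))
  gff <- readLines(paths["gff3"])
  expect_equal(sum(!startsWith(gff, "#")), nrow(reg$truth))
  back <- read_region(dir)
  expect_identical(back$sequence, reg$sequence)
  tr1 <- reg$truth; tr2 <- back$truth
  rownames(tr1) <- rownames(tr2) <- NULL
  expect_identical(tr1, tr2)
  expect_identical(as.data.frame(back$library), as.data.frame(reg$library))
  # feature-free region still emits valid files
  empty <- simulate_region(sim_config(region_length = 1e4, seed = 4,
                                      n_genes = 0))
  d2 <- withr::local_tempdir()
  p2 <- emit_truth(empty, d2)
  expect_equal(nrow(read_region(d2)$truth), 0)
})

test_that("planted footprint patterns have their defining structure", {
  cfg <- sim_config(seed = 6)
  bg <- make_background(3e4, 0.43, 8)
  # A: two identical 10-mers embrace the TE + captured fragment block
  fa <- plant_footprint(bg, "A_tsd_capture", list(tsd_length = 10,
                                                  position = 4000), cfg)
  f <- fa$truth[fa$truth$kind == "footprint", ]
  expect_equal(nchar(f$evidence), 10)
  expect_identical(substr(fa$sequence, f$start, f$start + 9), f$evidence)
  expect_identical(substr(fa$sequence, f$end - 9, f$end), f$evidence)
  # D: both flanks of the gene carry the array
  fd <- plant_footprint(bg, "D_tandem_flank", list(period = 3, copies = 8,
                                                   position = 4000), cfg)
  arr <- fd$truth[fd$truth$kind == "tandem_array", ]
  expect_equal(nrow(arr), 2)
  g <- fd$truth[fd$truth$kind == "gene", ]
  expect_true(max(arr$end[arr$end < g$start]) == g$start - 1)
  expect_true(min(arr$start[arr$start > g$end]) == g$end + 1)
  units <- arr$evidence
  expect_identical(substr(fd$sequence, arr$start[1], arr$end[1]),
                   strrep(units[1], 8))
  # E: retrocopy length equals the sum of the donor's exon lengths
  exons <- c("ATGCATGCAT", "GGGTTTCCCA", "TTACGGATCC")
  fe <- plant_footprint(bg, "E_retrocopy",
                        list(exon_seqs = exons, position = 4000), cfg)
  ge <- fe$truth[fe$truth$kind == "gene", ]
  expect_equal(ge$end - ge$start + 1, sum(nchar(exons)))
  expect_identical(substr(fe$sequence, ge$start, ge$end),
                   paste(exons, collapse = ""))
  expect_error(plant_footprint(bg, "Z_bogus", list(), cfg), "pattern")
})
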