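test_that("tandem-array detection handles canonical and planted arrays", {
  arr <- find_tandem_arrays("ATATATATAT", min_period = 2, max_period = 4,
                            min_copies = 3)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$period, 2)
  expect_equal(arr$copies, 5)
  expect_identical(arr$consensus_unit, "AT")

  cfg <- sim_config(region_length = 2e4, seed = 81,
                    tandems = list(tandem_spec(period = 3, copies = 8)))
  reg <- simulate_region(cfg)
  tr <- reg$truth[reg$truth$kind == "tandem_array", ]
  got <- find_tandem_arrays(reg$sequence, 2, 6, 5)
  hit <- got[abs(got$start - tr$start) <= 3 & abs(got$end - tr$end) <= 3, ]
  expect_gte(nrow(hit), 1)

  null <- make_background(1e4, 0.43, 82)
  expect_equal(nrow(find_tandem_arrays(null, 2, 6, 5)), 0)
  expect_error(find_tandem_arrays("ACGT", min_period = 0), "min_period")
})

test_that("tandem runs agree with a brute-force period scanner", {
  set.seed(83)
  for (rep in 1:10) {
    s <- chars_seq(random_dna_chars(500, 0.4))
    unit <- chars_seq(random_dna_chars(sample(2:5, 1), 0.4))
    s <- paste0(substr(s, 1, 200), strrep(unit, sample(4:9, 1)),
                substr(s, 201, 500))
    for (k in 2:6) {
      runs <- ltrfate:::period_runs(seq_chars(s), k)
      oracle <- oracle_period_runs(s, k)
      expect_equal(runs$start, oracle$start)
      expect_equal(runs$end, oracle$end)
    }
  }
})

test_that("pattern A scanning requires TE-gene adjacency plus an embracing TSD", {
  cfg <- sim_config(region_length = 4e4, seed = 84, n_genes = 1,
                    elements = list(plant_spec(family = "RLX01",
                                               age_years = 1e6)),
                    footprints = list(footprint_spec("A_tsd_capture",
                                                     tsd_length = 10)))
  reg <- simulate_region(cfg)
  te <- reg$truth[reg$truth$kind == "dna_te", ]
  genes <- truth_gene_summary(reg$truth)
  fp <- scan_tsd_capture(reg$sequence, te, genes)
  expect_equal(nrow(fp), 1)
  # at least the planted 10-mer; a chance adjacent match may lengthen it
  expect_gte(fp$score, 10)
  expect_lte(fp$score, 12)
  # evidence occurs verbatim at the reported coordinates
  expect_identical(substr(reg$sequence, fp$start, fp$start + fp$score - 1),
                   fp$evidence)
  expect_identical(substr(reg$sequence, fp$end - fp$score + 1, fp$end),
                   fp$evidence)
  # the ordinary intact element (5 bp TSD, no adjacent gene) triggers nothing
  ltr <- reg$truth[reg$truth$kind == "ltr_element", ]
  ltr_as_te <- data.frame(feature_id = ltr$feature_id, start = ltr$start,
                          end = ltr$end, class = ltr$class)
  far_genes <- genes[genes$feature_id == "G001", ]
  if (min(abs(far_genes$start - ltr$end), abs(ltr$start - far_genes$end)) > 2000)
    expect_equal(nrow(scan_tsd_capture(reg$sequence, ltr_as_te, far_genes)), 0)
  # genes but no TEs
  expect_equal(nrow(scan_tsd_capture(reg$sequence, te[0, ], genes)), 0)
})

test_that("shared-border scanning measures exact common terminal motifs", {
  cfg <- sim_config(region_length = 3e4, seed = 85, n_genes = 0,
                    footprints = list(footprint_spec("B_shared_border",
                                                     border_length = 6)))
  reg <- simulate_region(cfg)
  tr <- reg$truth
  fpt <- tr[tr$pattern %in% "B_shared_border", ]
  don <- tr[tr$feature_id == paste0(fpt$feature_id, ".donor"), ]
  acc <- tr[tr$feature_id == paste0(fpt$feature_id, ".acceptor"), ]
  got <- scan_shared_border(reg$sequence, c(acc$start, acc$end),
                            reg$sequence, c(don$start, don$end))
  expect_false(is.null(got))
  expect_gte(got$score, 6)
  expect_true(startsWith(got$evidence, fpt$evidence))
  # self-comparison: the full examined flank matches
  self <- scan_shared_border(reg$sequence, c(acc$start, acc$end),
                             reg$sequence, c(acc$start, acc$end),
                             max_flank = 50)
  expect_equal(self$score, 50)
  # unrelated flanks almost never share a 6-mer border; seeded trials
  set.seed(86)
  calls <- 0
  for (i in 1:50) {
    s1 <- chars_seq(random_dna_chars(600, 0.43))
    s2 <- chars_seq(random_dna_chars(600, 0.43))
    if (!is.null(scan_shared_border(s1, c(201, 400), s2, c(201, 400))))
      calls <- calls + 1
  }
  expect_lte(calls, 1)
  expect_error(scan_shared_border("ACGT", c(1, 4), "ACGT", c(1, 4)), "flank")
})

test_that("helitron capture flags only fully contained genes", {
  te <- data.frame(feature_id = "H1", start = 1000L, end = 5000L,
                   class = "Helitron")
  inside <- data.frame(feature_id = "g1", start = 2000L, end = 3000L)
  straddle <- data.frame(feature_id = "g2", start = 4500L, end = 6000L)
  expect_equal(nrow(scan_helitron_capture(te, inside)), 1)
  expect_equal(nrow(scan_helitron_capture(te, straddle)), 0)
  no_hel <- te; no_hel$class <- "hAT"
  expect_equal(nrow(scan_helitron_capture(no_hel, inside)), 0)
})

test_that("tandem-flank scanning demands arrays on both sides within the window", {
  cfg <- sim_config(region_length = 3e4, seed = 87, n_genes = 0,
                    footprints = list(footprint_spec("D_tandem_flank",
                                                     period = 3, copies = 8)))
  reg <- simulate_region(cfg)
  genes <- truth_gene_summary(reg$truth)
  arrays <- find_tandem_arrays(reg$sequence, 2, 6, 5)
  fp <- scan_tandem_flank(genes, arrays, window = 500)
  expect_equal(nrow(fp), 1)
  units <- strsplit(fp$evidence, "|", fixed = TRUE)[[1]]
  truth_units <- strsplit(reg$truth$evidence[
    reg$truth$pattern %in% "D_tandem_flank"], "|", fixed = TRUE)[[1]]
  expect_setequal(units, truth_units)
  # one-sided array: drop the left one
  left_end <- genes$start[1] - 1
  one_side <- arrays[arrays$start > genes$start[1], , drop = FALSE]
  expect_equal(nrow(scan_tandem_flank(genes, one_side, window = 500)), 0)
})

test_that("retrocopy flagging needs an intron-loss signature", {
  genes <- data.frame(feature_id = c("multi", "single", "multi2", "single2"),
                      start = c(1, 100, 200, 300),
                      end = c(50, 150, 250, 350),
                      n_exons = c(3L, 1L, 2L, 1L),
                      exon_bp = c(840L, 840L, 500L, 900L))
  hit <- flag_retrocopy(genes, data.frame(id1 = "multi", id2 = "single"))
  expect_equal(nrow(hit), 1)
  expect_identical(hit$gene_id, "single")
  # two multi-exon paralogs: no flag
  expect_equal(nrow(flag_retrocopy(genes, data.frame(id1 = "multi",
                                                     id2 = "multi2"))), 0)
  # single-single: no intron-loss evidence
  expect_equal(nrow(flag_retrocopy(genes, data.frame(id1 = "single",
                                                     id2 = "single2"))), 0)
  # length mismatch beyond tolerance: no flag
  expect_equal(nrow(flag_retrocopy(genes, data.frame(id1 = "multi2",
                                                     id2 = "single2"))), 0)
})
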