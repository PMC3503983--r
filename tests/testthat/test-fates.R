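test_that("mechanism mapping is total and matches the category semantics", {
  expected <- c(IntactLTR = "none",
                SoloWithTSD = "UR_intra",
                SoloWithoutTSD = "UR_inter",
                IntactWithoutTSD = "UR_intra",
                TruncatedSolo = "UR_inter_or_UR_intra_and_IR",
                ThreePrimeLTRDeleted = "IR",
                FivePrimeLTRDeleted = "IR",
                PartiallyDeleted = "IR",
                RecombinationComplex = "UR_inter")
  for (cat_i in fate_categories())
    expect_identical(mechanism_of(cat_i), unname(expected[cat_i]))
  expect_error(mechanism_of("NotAFate"), "unknown")
  expect_error(mechanism_of(fate_categories()), "unknown")
})

test_that("classification cascade handles the canonical structures", {
  lib <- make_repeat_library(n_ltr_families = 2, seed = 5)
  cfg <- sim_config(region_length = 4e4, seed = 51,
                    elements = list(
                      plant_spec(family = "RLX01", age_years = 1e6,
                                 fate = "IntactLTR"),
                      plant_spec(family = "RLX02", age_years = 1e6,
                                 fate = "SoloWithTSD")),
                    library = lib)
  reg <- simulate_region(cfg)
  el <- annotate_region(reg$sequence, reg$library)
  fates <- classify_fates(el, reg$library, reg$sequence)
  expect_setequal(fates$category, c("IntactLTR", "SoloWithTSD"))
  # element without any LTR-class sub-feature is not classifiable
  bogus <- structure(list(element_id = "x", family = "RLX01",
                          class = "Ty1/Copia", strand = "+", start = 10L,
                          end = 100L, source = "homology",
                          sub_features = data.frame(
                            role = "internal", start = 10L, end = 100L,
                            family = "RLX01", identity = 1, coverage = 0.02)),
                     class = "annotated_element")
  expect_error(classify_element(bogus, lib, reg$sequence), "not classifiable")
})

test_that("category counts partition the classified elements", {
  reg <- fate_region(seed = 52, n_elements = 18)
  el <- annotate_region(reg$sequence, reg$library)
  fates <- classify_fates(el, reg$library, reg$sequence)
  counts <- fate_count_table(fates)
  expect_equal(sum(counts), sum(!is.na(fates$category)))
  expect_named(counts, fate_categories())
  expect_true(all(counts >= 0))
})

test_that("region tendency balances inserted against inferred-removed bp", {
  lib <- make_repeat_library(n_ltr_families = 1, ltr_length = 1000,
                             internal_length = 6000, seed = 7)
  mk <- function(id, start, len, roles, covs) {
    structure(list(element_id = id, family = "RLX01", class = "Ty1/Copia",
                   strand = "+", start = start, end = start + len - 1L,
                   source = "homology",
                   sub_features = data.frame(
                     role = roles, start = start, end = start + len - 1L,
                     family = "RLX01", identity = 1, coverage = covs)),
              class = "annotated_element")
  }
  # full length 8 kb: intact-only region expands
  intacts <- structure(lapply(1:3, function(i)
    mk(paste0("e", i), 1000L + i * 10000L, 8000L, "five_prime_LTR", 1)),
    class = "annotated_elements")
  f1 <- data.frame(element_id = paste0("e", 1:3), family = "RLX01",
                   start = 1, end = 8000, category = "IntactLTR",
                   mechanism = "none")
  t1 <- region_tendency(intacts, f1, lib)
  expect_identical(t1$tendency, "E")
  expect_equal(t1$bp_removed_inferred, 0)
  # solo-only region (1 kb observed of an 8 kb element) contracts
  solos <- structure(lapply(1:3, function(i)
    mk(paste0("s", i), 1000L + i * 10000L, 1000L, "LTR", 1)),
    class = "annotated_elements")
  f2 <- data.frame(element_id = paste0("s", 1:3), family = "RLX01",
                   start = 1, end = 1000, category = "SoloWithTSD",
                   mechanism = "UR_intra")
  t2 <- region_tendency(solos, f2, lib)
  expect_identical(t2$tendency, "C")
  expect_equal(t2$bp_removed_inferred, 3 * 7000)
  # 10 intact + 2 solos: insertion dominates
  mixed <- structure(c(unclass(structure(lapply(1:10, function(i)
    mk(paste0("m", i), 1000L + i * 9000L, 8000L, "five_prime_LTR", 1)),
    class = "annotated_elements")),
    unclass(solos)[1:2]), class = "annotated_elements")
  f3 <- data.frame(element_id = c(paste0("m", 1:10), "s1", "s2"),
                   family = "RLX01", start = 1, end = 1,
                   category = c(rep("IntactLTR", 10), rep("SoloWithTSD", 2)),
                   mechanism = "x")
  expect_identical(region_tendency(mixed, f3, lib)$tendency, "E")
  expect_error(region_tendency(structure(list(),
                                         class = "annotated_elements"),
                               f3, lib), "tendency")
})
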