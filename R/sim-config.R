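# Simulation configuration: the study conditions for the synthetic regions.

#' The nine element-fate categories
#'
#' Every LTR-derived element is assigned exactly one of these structural
#' fates: an intact element (with or without a recognisable target-site
#' duplication), a solo LTR (with or without TSD), a truncated solo LTR, an
#' element missing its 3' or 5' LTR, an element with internal/terminal
#' deletions but both termini still representable, or a recombination
#' complex joining parts of two families.
#'
#' @return character vector of the nine category identifiers.
#' @export
fate_categories <- function() {
  c("IntactLTR", "SoloWithTSD", "SoloWithoutTSD", "IntactWithoutTSD",
    "TruncatedSolo", "ThreePrimeLTRDeleted", "FivePrimeLTRDeleted",
    "PartiallyDeleted", "RecombinationComplex")
}

#' @rdname fate_categories
#' @export
fate_labels <- function() {
  c(IntactLTR = "Intact LTR",
    SoloWithTSD = "Solo w/TSD",
    SoloWithoutTSD = "Solo w/o TSD",
    IntactWithoutTSD = "Intact LTR w/o TSD",
    TruncatedSolo = "Truncated Solo",
    ThreePrimeLTRDeleted = "3' LTR deleted",
    FivePrimeLTRDeleted = "5' LTR deleted",
    PartiallyDeleted = "5' and/or 3' partially deleted",
    RecombinationComplex = "Recombination complex")
}

FOOTPRINT_PATTERNS <- c("A_tsd_capture", "B_shared_border",
                        "C_helitron_capture", "D_tandem_flank", "E_retrocopy")

#' Specify one LTR element to plant
#'
#' @param family library family name, or `NA` to cycle through the library.
#' @param age_years insertion age in years (>= 0); at age 0 the two planted
#'   LTR copies are identical.
#' @param fate one of [fate_categories()].
#' @param tsd_length target-site-duplication length in bp (0--20); 5 is the
#'   canonical LTR-retrotransposon value.
#' @param position 1-based background offset, or `"random"`.
#' @param nest_in feature id of a previously planted element to nest inside,
#'   or `NA`.
#' @param trunc_fraction for `TruncatedSolo`, retained fraction of the LTR.
#' @param family2 for `RecombinationComplex`, the second family (or `NA`).
#' @return a `plant_spec` list.
#' @export
plant_spec <- function(family = NA, age_years = 1e6, fate = "IntactLTR",
                       tsd_length = 5, position = "random", nest_in = NA,
                       trunc_fraction = 0.4, family2 = NA) {
  fate <- match.arg(fate, fate_categories())
  if (!is_scalar_number(age_years) || age_years < 0)
    stopf("age_years must be >= 0")
  if (!is_count(tsd_length) || tsd_length > 20)
    stopf("tsd_length must be an integer in [0, 20]")
  if (fate == "SoloWithTSD" && tsd_length == 0)
    stopf("fate SoloWithTSD requires tsd_length > 0")
  if (fate %in% c("IntactLTR") && tsd_length == 0)
    stopf("fate IntactLTR requires tsd_length > 0")
  if (!(identical(position, "random") || is_count(position)))
    stopf("position must be a positive integer offset or \"random\"")
  if (fate == "TruncatedSolo" &&
      (trunc_fraction <= 0 || trunc_fraction >= 0.8))
    stopf("trunc_fraction must be in (0, 0.8) for a truncated solo")
  structure(list(family = family, age_years = age_years, fate = fate,
                 tsd_length = as.integer(tsd_length), position = position,
                 nest_in = nest_in, trunc_fraction = trunc_fraction,
                 family2 = family2),
            class = "plant_spec")
}

#' Specify one gene-movement footprint to plant
#'
#' @param pattern one of `"A_tsd_capture"` (TE plus captured gene fragment
#'   embraced by one TSD), `"B_shared_border"` (donor and acceptor gene
#'   copies sharing an identical border motif on one side),
#'   `"C_helitron_capture"` (gene inside Helitron termini),
#'   `"D_tandem_flank"` (gene flanked by tandem arrays on both sides),
#'   `"E_retrocopy"` (intronless copy of a planted multi-exon gene).
#' @param tsd_length pattern A TSD length (bp).
#' @param border_length pattern B shared-border length (bp).
#' @param period,copies pattern D tandem-array unit length and copy number.
#' @param source_gene pattern E donor gene id (`NA`: first planted
#'   multi-exon gene).
#' @param gene_length length of the moved gene copy (patterns A--D).
#' @param te_length length of the capturing TE (patterns A, C).
#' @param position 1-based background offset or `"random"`.
#' @return a `footprint_spec` list.
#' @export
footprint_spec <- function(pattern, tsd_length = 10, border_length = 6,
                           period = 3, copies = 8, source_gene = NA,
                           gene_length = 900, te_length = 1200,
                           position = "random") {
  if (!pattern %in% FOOTPRINT_PATTERNS)
    stopf("unknown footprint pattern '%s'", pattern)
  if (pattern == "A_tsd_capture" && (!is_count(tsd_length) || tsd_length < 4))
    stopf("pattern A needs tsd_length >= 4")
  if (pattern == "B_shared_border" && (!is_count(border_length) || border_length < 1))
    stopf("pattern B needs border_length >= 1")
  if (pattern == "D_tandem_flank" && (!is_count(period) || !is_count(copies) || copies < 2))
    stopf("pattern D needs integer period and copies >= 2")
  structure(list(pattern = pattern, tsd_length = as.integer(tsd_length),
                 border_length = as.integer(border_length),
                 period = as.integer(period), copies = as.integer(copies),
                 source_gene = source_gene, gene_length = as.integer(gene_length),
                 te_length = as.integer(te_length), position = position),
            class = "footprint_spec")
}

#' Specify one DNA transposon to plant
#' @param family library DNA family (or `NA` to cycle).
#' @param age_years divergence age from the consensus, years.
#' @param position 1-based background offset or `"random"`.
#' @export
dna_spec <- function(family = NA, age_years = 1e6, position = "random") {
  structure(list(family = family, age_years = age_years, position = position),
            class = "dna_spec")
}

#' Specify one tandem-repeat array to plant
#' @param period repeat unit length (bp).
#' @param copies number of unit copies (>= 2).
#' @param position 1-based background offset or `"random"`.
#' @export
tandem_spec <- function(period = 3, copies = 8, position = "random") {
  if (!is_count(period) || period < 1 || !is_count(copies) || copies < 2)
    stopf("tandem array needs period >= 1 and copies >= 2")
  structure(list(period = as.integer(period), copies = as.integer(copies),
                 position = position), class = "tandem_spec")
}

#' Simulation configuration
#'
#' Bundles the background model (length, G+C), the mutation model
#' (substitution rate `r`, transition/transversion ratio `kappa`), the seed,
#' and the lists of features to plant.  Identical configurations (same seed
#' included) produce byte-identical regions.
#'
#' @param region_length background length in bp (>= 10 kb); planted
#'   insertions extend the final sequence beyond this.
#' @param gc_fraction background G+C proportion, in (0, 1).
#' @param rate substitution rate `r` (substitutions/site/year); default
#'   1.3e-8, the standard rate for grass LTR sequences.
#' @param kappa transition/transversion rate ratio.
#' @param seed master integer seed; per-feature streams are derived from it.
#' @param elements list of [plant_spec()].
#' @param dna_tes list of [dna_spec()].
#' @param tandems list of [tandem_spec()].
#' @param footprints list of [footprint_spec()].
#' @param n_genes number of background genes to annotate (3 exons each).
#' @param library a `repeat_library`, or `NULL` to generate one from `seed`.
#' @param min_gap minimum background gap between planted features (bp).
#' @param region_id sequence name used in output files.
#' @return a `sim_config` list.
#' @export
sim_config <- function(region_length = 1e5, gc_fraction = 0.43,
                       rate = 1.3e-8, kappa = 2, seed = 1,
                       elements = list(), dna_tes = list(), tandems = list(),
                       footprints = list(), n_genes = 2, library = NULL,
                       min_gap = 2000, region_id = "simregion") {
  if (!is_scalar_number(region_length) || region_length < 1e4)
    stopf("region_length must be >= 10 kb")
  if (!is_scalar_number(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1)
    stopf("gc_fraction must be in (0, 1)")
  if (!is_scalar_number(rate) || rate <= 0) stopf("rate must be > 0")
  if (!is_scalar_number(kappa) || kappa <= 0) stopf("kappa must be > 0")
  if (!is_count(seed)) stopf("seed must be a non-negative integer")
  if (is.null(library)) library <- make_repeat_library(seed = seed)
  structure(list(region_length = as.integer(region_length),
                 gc_fraction = gc_fraction, rate = rate, kappa = kappa,
                 seed = as.integer(seed), elements = elements,
                 dna_tes = dna_tes, tandems = tandems,
                 footprints = footprints, n_genes = n_genes,
                 library = library, min_gap = as.integer(min_gap),
                 region_id = region_id),
            class = "sim_config")
}
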