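# Element-fate classification, removal-mechanism inference, and the
# region-level contraction/expansion balance.
#
# Solo LTRs arise when unequal homologous recombination (UR) between the
# two LTRs of one element (intra-element) or between elements
# (inter-element) deletes the internal region; illegitimate recombination
# (IR) removes sequence without leaving solo LTRs.  The mechanism is fully
# determined by the structural category.

LTR_ROLES <- c("five_prime_LTR", "three_prime_LTR", "LTR", "partial_LTR")
INT_ROLES <- c("internal", "partial_internal")

# tsd_min is 5 here (stricter than the annotator's detect_tsd default of
# 4): a 4-mer recurs by chance at ~1/256 per placement, too often to count
# as evidence for the With/WithoutTSD distinction, while real LTR TSDs are
# canonically 5 bp.
fate_params <- function(full_ltr_cov = 0.8, min_internal_cov = 0.5,
                        solo_isolation = 500, alt_family_bp = 300,
                        tsd_min = 5, tsd_max = 20, tsd_window = 2) {
  list(full_ltr_cov = full_ltr_cov, min_internal_cov = min_internal_cov,
       solo_isolation = solo_isolation, alt_family_bp = alt_family_bp,
       tsd_min = tsd_min, tsd_max = tsd_max, tsd_window = tsd_window)
}

ltr_sub_coverage <- function(sf, element_family, library) {
  cov <- sf$coverage
  for (i in seq_len(nrow(sf))) {
    if (!is.na(cov[i])) next
    fam <- if (!is.na(sf$family[i])) sf$family[i] else element_family
    cons <- lib_seq(library, fam, "LTR")
    cov[i] <- if (is.null(cons)) NA_real_
              else (sf$end[i] - sf$start[i] + 1L) / nchar(cons)
  }
  cov
}

element_has_tsd <- function(element, sequence, p) {
  if (is.null(sequence)) return(FALSE)
  # boundary uncertainty comes only from divergence: when the element's
  # LTR evidence is at 100% identity the boundaries are exact and strict
  # abutment applies, which suppresses chance flank matches
  ids <- element$sub_features$identity
  win <- if (length(ids) && all(is.na(ids) | ids >= 0.999)) 0L
         else p$tsd_window
  flank_ok <- element$start - 1L >= p$tsd_min + win &&
    nchar(sequence) - element$end >= p$tsd_min + win
  if (!flank_ok) return(FALSE)
  !is.null(detect_tsd(sequence, element$start, element$end,
                      min_len = p$tsd_min, max_len = p$tsd_max,
                      window = win))
}

#' Classify one annotated element into its fate category
#'
#' Decision cascade over the element's sub-features: two full-length LTRs
#' with a well-covered internal region give an intact element (with/without
#' TSD); a lone full-length LTR gives a solo (with/without TSD); a partial
#' lone LTR a truncated solo; an internal region with exactly one LTR a 3'-
#' or 5'-LTR-deleted element; two termini with poorly covered internal a
#' partially deleted element; and sub-features best matching two different
#' families a recombination complex.
#'
#' @param element an `annotated_element`.
#' @param library a `repeat_library`.
#' @param sequence the region sequence (for TSD detection).
#' @param params a [fate_params()] list of thresholds.
#' @return one of [fate_categories()].
#' @export
classify_element <- function(element, library, sequence = NULL,
                             params = fate_params()) {
  p <- params
  sf <- element$sub_features
  ltr_sf <- sf[sf$role %in% LTR_ROLES, , drop = FALSE]
  int_sf <- sf[sf$role %in% INT_ROLES, , drop = FALSE]
  if (!nrow(ltr_sf))
    stopf("element %s has no LTR-class sub-features; not classifiable",
          element$element_id %||% "?")

  # recombination complex: internal evidence from two different families,
  # or two full LTRs of different families joined through one element
  if (nrow(int_sf)) {
    bp <- tapply(int_sf$end - int_sf$start + 1L, int_sf$family, sum)
    strong <- names(bp)[bp >= p$alt_family_bp]
    if (length(strong) >= 2L) return("RecombinationComplex")
  }
  ltr_fams <- unique(ltr_sf$family[!is.na(ltr_sf$family)])
  if (length(ltr_fams) >= 2L && nrow(int_sf)) return("RecombinationComplex")

  cov <- ltr_sub_coverage(ltr_sf, element$family, library)
  full <- !is.na(cov) & cov >= p$full_ltr_cov
  cons_int <- lib_seq(library, element$family, "internal")
  int_cov <- if (is.null(cons_int) || !nrow(int_sf)) 0
             else min(1, sum(int_sf$end - int_sf$start + 1L) / nchar(cons_int))

  five <- ltr_sf$role == "five_prime_LTR"
  three <- ltr_sf$role == "three_prime_LTR"
  both_term <- any(five) && any(three)

  if (both_term && all(full[five | three])) {
    if (int_cov >= p$min_internal_cov) {
      return(if (element_has_tsd(element, sequence, p)) "IntactLTR"
             else "IntactWithoutTSD")
    }
    return("PartiallyDeleted")
  }
  if (both_term) return("PartiallyDeleted") # termini present, one degraded

  if (nrow(ltr_sf) == 1L) {
    if (int_cov >= p$min_internal_cov) {
      # one LTR plus internal: which LTR is missing?
      before <- ltr_sf$end[1L] <= min(int_sf$start)
      after <- ltr_sf$start[1L] >= max(int_sf$end)
      minus <- identical(element$strand, "-")
      if (before && !after) return(if (minus) "FivePrimeLTRDeleted"
                                   else "ThreePrimeLTRDeleted")
      if (after && !before) return(if (minus) "ThreePrimeLTRDeleted"
                                   else "FivePrimeLTRDeleted")
      return("PartiallyDeleted") # orientation ambiguous
    }
    if (full[1L]) {
      return(if (element_has_tsd(element, sequence, p)) "SoloWithTSD"
             else "SoloWithoutTSD")
    }
    return("TruncatedSolo")
  }
  # several LTR fragments, no internal evidence
  if (int_cov >= p$min_internal_cov) return("PartiallyDeleted")
  if (any(full)) {
    return(if (element_has_tsd(element, sequence, p)) "SoloWithTSD"
           else "SoloWithoutTSD")
  }
  "TruncatedSolo"
}

#' Removal mechanism implied by a fate category
#'
#' A fixed, total mapping: solo LTRs with TSD arise by intra-element
#' unequal recombination (UR intra); solos without TSD and recombination
#' complexes by inter-element UR; LTR-deleted and partially deleted
#' elements by illegitimate recombination (IR); truncated solos by UR
#' (inter) or UR (intra) combined with IR; intact elements record none.
#'
#' @param category one of [fate_categories()].
#' @return one of `"UR_intra"`, `"UR_inter"`, `"IR"`,
#'   `"UR_inter_or_UR_intra_and_IR"`, `"none"`.
#' @export
mechanism_of <- function(category) {
  map <- c(IntactLTR = "none",
           SoloWithTSD = "UR_intra",
           SoloWithoutTSD = "UR_inter",
           IntactWithoutTSD = "UR_intra",
           TruncatedSolo = "UR_inter_or_UR_intra_and_IR",
           ThreePrimeLTRDeleted = "IR",
           FivePrimeLTRDeleted = "IR",
           PartiallyDeleted = "IR",
           RecombinationComplex = "UR_inter")
  if (length(category) != 1L || !category %in% names(map))
    stopf("unknown fate category '%s'", paste(category, collapse = ","))
  unname(map[category])
}

#' Classify all elements of a region
#'
#' @param elements `annotated_elements` from [assemble_elements()].
#' @param library a `repeat_library`.
#' @param sequence region sequence (for TSD detection).
#' @param params [fate_params()].
#' @return data frame: `element_id`, `family`, `start`, `end`, `category`,
#'   `mechanism`. Elements that cannot be classified get `NA` with a
#'   warning.
#' @export
classify_fates <- function(elements, library, sequence = NULL,
                           params = fate_params()) {
  rows <- lapply(elements, function(e) {
    cat_i <- tryCatch(classify_element(e, library, sequence, params),
                      error = function(err) {
                        warning(conditionMessage(err), call. = FALSE)
                        NA_character_
                      })
    data.frame(element_id = e$element_id, family = e$family,
               start = e$start, end = e$end, category = cat_i,
               mechanism = if (is.na(cat_i)) NA_character_
                           else mechanism_of(cat_i),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(element_id = character(0), family = character(0),
                      start = integer(0), end = integer(0),
                      category = character(0), mechanism = character(0)))
  do.call(rbind, rows)
}

#' Count elements per fate category
#' @param fates data frame from [classify_fates()].
#' @return named integer vector over all nine categories.
#' @export
fate_count_table <- function(fates) {
  counts <- table(factor(fates$category, levels = fate_categories()))
  stats::setNames(as.integer(counts), fate_categories())
}

#' Region contraction/expansion tendency
#'
#' Balances the LTR-derived base pairs present in the region
#' (`bp_inserted`) against the base pairs inferred removed
#' (`bp_removed_inferred`: for every element, the family's reconstructed
#' full length minus the observed length, floored at zero).  Returns `"E"`
#' (expansion) when insertion outweighs inferred removal, `"C"`
#' (contraction) otherwise; both totals are reported so other rules can be
#' applied.
#'
#' @param elements `annotated_elements`.
#' @param fates data frame from [classify_fates()].
#' @param library a `repeat_library`.
#' @return list: `tendency` ("C"/"E"), `bp_inserted`,
#'   `bp_removed_inferred`, `counts`.
#' @export
region_tendency <- function(elements, fates, library) {
  if (!length(elements)) stopf("no elements: tendency undefined")
  obs <- vapply(elements, function(e) e$end - e$start + 1L, integer(1))
  full <- vapply(elements, function(e) {
    fl <- lib_full_length(library, e$family)
    if (is.na(fl)) 0L else as.integer(fl)
  }, integer(1))
  removed <- pmax(full - obs, 0L)
  list(tendency = if (sum(obs) > sum(removed)) "E" else "C",
       bp_inserted = sum(obs),
       bp_removed_inferred = sum(removed),
       counts = fate_count_table(fates))
}
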