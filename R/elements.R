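# Assembly of structural LTR pairs and library hits into annotated
# elements.  Structural evidence outranks homology evidence; pairs are
# processed innermost-first so that a nested guest claims its own hits
# before the host does.

new_element <- function(element_id, family, class, strand, start, end,
                        source, sub_features) {
  structure(list(element_id = element_id, family = family, class = class,
                 strand = strand, start = as.integer(start),
                 end = as.integer(end), source = source,
                 sub_features = sub_features),
            class = "annotated_element")
}

sub_feature_df <- function(role = character(0), start = integer(0),
                           end = integer(0), family = NA_character_,
                           identity = NA_real_, coverage = NA_real_) {
  data.frame(role = role, start = as.integer(start), end = as.integer(end),
             family = family, identity = identity, coverage = coverage,
             stringsAsFactors = FALSE)
}

majority_family <- function(hits) {
  if (!nrow(hits)) return("unknown")
  bp <- tapply(hits$end - hits$start + 1L, hits$family, sum)
  names(bp)[which.max(bp)]
}

majority_strand <- function(hits) {
  if (!nrow(hits)) return("+")
  if (sum(hits$strand == "-") > sum(hits$strand == "+")) "-" else "+"
}

#' Assemble LTR pairs and library hits into annotated elements
#'
#' Each accepted structural pair becomes an element whose inter-LTR hits
#' supply the family label; library hits not claimed by any pair are
#' clustered by proximity into solo/truncated/partial element candidates.
#'
#' @param pairs data frame from [find_ltr_pairs()] (ideally with
#'   `resolve = "none"`, so conflicts can be settled here with homology
#'   evidence).
#' @param hits data frame from [match_library()].
#' @param library a `repeat_library` (supplies consensus geometry).
#' @param cluster_gap maximum gap (bp) between hits merged into one
#'   homology-only element.
#' @param min_pair_support minimum fraction of a pair's inter-LTR interval
#'   that must be covered by internal-consensus hits for the pair to be
#'   accepted as one element.  Two solo LTRs of the same family can form a
#'   perfectly good structural pair; the empty inter-LTR interval is what
#'   distinguishes them from a real element.  Ignored when no internal
#'   hits are available at all.
#' @param max_span_factor a pair spanning more than this multiple of its
#'   family's consensus full length is rejected as a cross-element
#'   artefact, unless a complete candidate pair nested inside accounts for
#'   the extra length.
#' @return a list of `annotated_element` objects (class
#'   `annotated_elements`).
#' @export
assemble_elements <- function(pairs, hits, library, cluster_gap = 500,
                              min_pair_support = 0.2, max_span_factor = 1.3) {
  elements <- list()
  consumed <- rep(FALSE, nrow(hits))
  if (nrow(pairs)) {
    pairs <- resolve_pairs_with_hits(pairs, hits, min_pair_support,
                                     library, max_span_factor)
  }
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$span), , drop = FALSE] # innermost first
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      # a few bp of slop: self-comparison boundaries and library-hit
      # boundaries can disagree by 1-2 bases at the element termini
      inside <- !consumed & hits$start >= p$left_start - 10L &
        hits$end <= p$right_end + 10L
      consumed[inside] <- TRUE
      hin <- hits[inside, , drop = FALSE]
      # internal hits mostly inside the inter-LTR interval (a few bp of
      # boundary slop from ungapped extension is tolerated)
      in_ov <- pmin(hin$end, p$right_start - 1L) -
        pmax(hin$start, p$left_end + 1L) + 1L
      internal <- hin[hin$role == "internal" &
                        in_ov >= 0.5 * (hin$end - hin$start + 1L), ,
                      drop = FALSE]
      ltrh <- hin[hin$role == "LTR", , drop = FALSE]
      fam <- if (nrow(internal)) majority_family(internal)
             else if (nrow(ltrh)) majority_family(ltrh) else "unknown"
      cls <- class_of_family(library, fam)
      # snap boundaries to near-full-length LTR consensus hits: extension
      # against the library is bounded by the consensus ends, so those
      # boundaries are base-exact, while self-comparison extension can
      # wander a few bp into the flanks
      l_iv <- c(p$left_start, p$left_end)
      r_iv <- c(p$right_start, p$right_end)
      if (nrow(ltrh)) {
        snap <- function(iv) {
          ov <- vapply(seq_len(nrow(ltrh)), function(j)
            interval_overlap(iv[1], iv[2], ltrh$start[j], ltrh$end[j]),
            numeric(1))
          j <- which(ov >= 0.5 * (iv[2] - iv[1] + 1) & ltrh$coverage >= 0.9)
          if (length(j)) {
            j <- j[which.max(ov[j])]
            c(ltrh$start[j], ltrh$end[j])
          } else iv
        }
        l_iv <- snap(l_iv)
        r_iv <- snap(r_iv)
      }
      sf <- rbind(
        sub_feature_df("five_prime_LTR", l_iv[1], l_iv[2], fam,
                       p$identity, NA_real_),
        if (nrow(internal))
          sub_feature_df(internal$role, internal$start, internal$end,
                         internal$family, internal$identity, internal$coverage),
        sub_feature_df("three_prime_LTR", r_iv[1], r_iv[2], fam,
                       p$identity, NA_real_))
      elements[[length(elements) + 1L]] <-
        new_element(NA_character_, fam, cls, majority_strand(hin),
                    l_iv[1], r_iv[2], "structural", sf)
    }
  }
  rest <- hits[!consumed, , drop = FALSE]
  if (nrow(rest)) {
    rest <- rest[order(rest$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(rest$start[-1L] -
                                     cummax(rest$end)[-nrow(rest)] > cluster_gap)))
    for (g in unique(grp)) {
      h <- rest[grp == g, , drop = FALSE]
      fam <- majority_family(h)
      int_iv <- h[h$role == "internal", , drop = FALSE]
      roles <- character(nrow(h))
      for (r in seq_len(nrow(h))) {
        if (h$role[r] == "internal") {
          roles[r] <- if (h$coverage[r] >= 0.8) "internal" else "partial_internal"
        } else if (h$role[r] == "LTR") {
          if (!nrow(int_iv)) roles[r] <- "LTR"
          else if (h$end[r] <= min(int_iv$start)) roles[r] <- "five_prime_LTR"
          else if (h$start[r] >= max(int_iv$end)) roles[r] <- "three_prime_LTR"
          else roles[r] <- "LTR"
        } else roles[r] <- h$role[r]
      }
      sf <- sub_feature_df(roles, h$start, h$end, h$family, h$identity,
                           h$coverage)
      elements[[length(elements) + 1L]] <-
        new_element(NA_character_, fam, class_of_family(library, fam),
                    majority_strand(h), min(h$start), max(h$end),
                    "homology", sf)
    }
  }
  if (length(elements)) {
    ord <- order(vapply(elements, function(e) e$start, integer(1)))
    elements <- elements[ord]
    for (i in seq_along(elements))
      elements[[i]]$element_id <- sprintf("elem%03d", i)
  }
  structure(elements, class = "annotated_elements")
}

# Joint resolution of structural pair conflicts using homology evidence.
# A pair joining the two LTRs of one element always has higher LTR-LTR
# identity than a pair joining LTRs of two different same-family elements
# (2rt vs 4rt expected divergence), so conflicts rank by descending
# identity; exact ties (e.g. several identical young copies) go to the
# shortest outer span, which keeps neighbouring elements separate.  Pairs
# whose inter-LTR interval carries no internal-consensus coverage are two
# independent solo LTRs, not one element, and are rejected outright.
resolve_pairs_with_hits <- function(pairs, hits, min_pair_support,
                                    library = NULL, max_span_factor = 1.3) {
  if (!nrow(pairs)) return(pairs)
  int_hits <- hits[hits$role == "internal", , drop = FALSE]
  ltr_hits <- hits[hits$role == "LTR", , drop = FALSE]
  n <- nrow(pairs)

  # the family suggested by LTR-consensus hits under the pair's own LTRs
  pair_family <- vapply(seq_len(n), function(i) {
    if (!nrow(ltr_hits)) return(NA_character_)
    ov <- vapply(seq_len(nrow(ltr_hits)), function(j)
      max(interval_overlap(pairs$left_start[i], pairs$left_end[i],
                           ltr_hits$start[j], ltr_hits$end[j]),
          interval_overlap(pairs$right_start[i], pairs$right_end[i],
                           ltr_hits$start[j], ltr_hits$end[j])),
      numeric(1))
    on_ltr <- ltr_hits[ov >= 0.5 * (ltr_hits$end - ltr_hits$start + 1L), ,
                       drop = FALSE]
    if (!nrow(on_ltr)) NA_character_ else majority_family(on_ltr)
  }, character(1))

  if (nrow(int_hits)) {
    # a real element carries internal sequence of its own family between
    # its LTRs; a pair of two independent solo LTRs does not, even when an
    # unrelated element happens to sit between them
    support <- vapply(seq_len(n), function(i) {
      lo <- pairs$left_end[i] + 1L
      hi <- pairs$right_start[i] - 1L
      if (hi < lo) return(0)
      ih <- if (is.na(pair_family[i])) int_hits
            else int_hits[int_hits$family == pair_family[i], , drop = FALSE]
      if (!nrow(ih)) return(0)
      ov <- sum(vapply(seq_len(nrow(ih)), function(j)
        interval_overlap(lo, hi, ih$start[j], ih$end[j]), numeric(1)))
      ov / (hi - lo + 1L)
    }, numeric(1))
    keep <- support >= min_pair_support
    pairs <- pairs[keep, , drop = FALSE]
    pair_family <- pair_family[keep]
    n <- nrow(pairs)
  }
  if (!n) return(pairs)

  # does any complete candidate pair lie fully inside pair i's inter-LTR
  # interval?  (the signature of a nested guest element)
  has_inside_pair <- vapply(seq_len(n), function(i) {
    lo <- pairs$left_end[i] + 1L
    hi <- pairs$right_start[i] - 1L
    if (hi < lo) return(FALSE)
    any(vapply(seq_len(n), function(q)
      q != i && pairs$left_start[q] > lo && pairs$right_end[q] < hi,
      logical(1)))
  }, logical(1))

  # a pair spanning far more than its family's full length is two
  # elements, not one -- unless a nested guest accounts for the excess
  if (!is.null(library)) {
    full_len <- vapply(pair_family, function(f)
      if (is.na(f)) NA_real_ else as.numeric(lib_full_length(library, f)),
      numeric(1))
    oversized <- !is.na(full_len) & pairs$span > max_span_factor * full_len &
      !has_inside_pair
    pairs <- pairs[!oversized, , drop = FALSE]
    pair_family <- pair_family[!oversized]
    has_inside_pair <- has_inside_pair[!oversized]
    n <- nrow(pairs)
    if (!n) return(pairs)
  }

  # a pair joining LTRs of two different elements encloses a third LTR
  # copy in its inter-LTR interval; a genuine element encloses one only
  # when a complete (candidate-paired) guest element is nested inside
  enclosing <- vapply(seq_len(n), function(i) {
    if (!nrow(ltr_hits)) return(FALSE)
    lo <- pairs$left_end[i] + 1L
    hi <- pairs$right_start[i] - 1L
    if (hi < lo) return(FALSE)
    hl <- ltr_hits$end - ltr_hits$start + 1L
    inside <- which(vapply(seq_len(nrow(ltr_hits)), function(j)
      interval_overlap(lo, hi, ltr_hits$start[j], ltr_hits$end[j]),
      numeric(1)) >= 0.5 * hl)
    if (!length(inside)) return(FALSE)
    # exempt LTR hits explained by a candidate pair lying fully inside
    for (j in inside) {
      explained <- FALSE
      for (q in seq_len(n)) {
        if (q == i) next
        if (pairs$left_start[q] > lo && pairs$right_end[q] < hi &&
            max(interval_overlap(pairs$left_start[q], pairs$left_end[q],
                                 ltr_hits$start[j], ltr_hits$end[j]),
                interval_overlap(pairs$right_start[q], pairs$right_end[q],
                                 ltr_hits$start[j], ltr_hits$end[j])) >=
              0.5 * hl[j]) {
          explained <- TRUE
          break
        }
      }
      if (!explained) return(TRUE)
    }
    FALSE
  }, logical(1))
  pairs <- pairs[!enclosing, , drop = FALSE]
  if (!nrow(pairs)) return(pairs)
  resolve_pair_conflicts(pairs[order(-pairs$identity, pairs$span,
                                     pairs$left_start), , drop = FALSE])
}

class_of_family <- function(library, family) {
  i <- which(library$family == family)
  if (length(i)) library$class[i[1L]] else "Unclassified"
}

#' @export
print.annotated_elements <- function(x, ...) {
  cat(sprintf("<annotated_elements> %d elements\n", length(x)))
  if (length(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Flatten annotated elements to a data frame (one row per element)
#' @param x an `annotated_elements` list.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @export
as.data.frame.annotated_elements <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  if (!length(x)) {
    return(data.frame(element_id = character(0), family = character(0),
                      class = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      source = character(0), n_sub = integer(0)))
  }
  do.call(rbind, lapply(x, function(e)
    data.frame(element_id = e$element_id, family = e$family,
               class = e$class, strand = e$strand, start = e$start,
               end = e$end, source = e$source,
               n_sub = nrow(e$sub_features), stringsAsFactors = FALSE)))
}

#' Annotate a region end-to-end
#'
#' Convenience wrapper: runs [find_ltr_pairs()] and [match_library()], then
#' [assemble_elements()].
#'
#' @param sequence character scalar.
#' @param library a `repeat_library`.
#' @param pair_params,match_params named lists overriding the defaults of
#'   the two search stages.
#' @param cluster_gap see [assemble_elements()].
#' @return `annotated_elements`.
#' @export
annotate_region <- function(sequence, library, pair_params = list(),
                            match_params = list(), cluster_gap = 500) {
  if (is.null(pair_params$resolve)) pair_params$resolve <- "none"
  pairs <- do.call(find_ltr_pairs, c(list(sequence = sequence), pair_params))
  lib_ltr <- library[library$role %in% c("LTR", "internal"), , drop = FALSE]
  lib_ltr <- validate_repeat_library(lib_ltr)
  hits <- do.call(match_library,
                  c(list(sequence = sequence, library = lib_ltr), match_params))
  assemble_elements(pairs, hits, library, cluster_gap = cluster_gap)
}
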