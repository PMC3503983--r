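# Scanners for DSB-repair / element-capture gene-movement footprints:
#   A  a TSD embracing a TE plus a captured gene fragment
#   B  donor and acceptor gene copies sharing an identical border motif
#   C  a gene contained inside Helitron termini
#   D  a gene flanked by tandem-repeat arrays on both sides
#   E  an intronless retrocopy of a multi-exon paralog
# All motif evidence is exact-match; every evidence string occurs verbatim
# at its reported coordinates.

footprint_df <- function(pattern = character(0), start = integer(0),
                         end = integer(0), gene_id = NA_character_,
                         partner_id = NA_character_,
                         evidence = NA_character_, score = integer(0)) {
  n <- length(pattern)
  data.frame(pattern = pattern, start = as.integer(start),
             end = as.integer(end),
             gene_id = rep_len(as.character(gene_id), n),
             partner_id = rep_len(as.character(partner_id), n),
             evidence = rep_len(as.character(evidence), n),
             score = as.integer(score), stringsAsFactors = FALSE)
}

# maximal agreement runs of s[i] == s[i + k]; internal engine shared with
# the brute-force oracle comparison in the tests
period_runs <- function(chars, k, max_mismatch_frac = 0) {
  n <- length(chars)
  if (n < 2L * k) return(data.frame(start = integer(0), end = integer(0)))
  eq <- chars[seq_len(n - k)] == chars[(k + 1L):n]
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (max_mismatch_frac > 0 && nrow(runs) > 1L) {
    # greedily bridge short mismatch gaps while the overall mismatch
    # fraction of the merged run stays within budget
    merged <- runs[1L, ]
    for (i in 2L:nrow(runs)) {
      j <- nrow(merged)
      cand_len <- runs$end[i] - merged$start[j] + 1L
      mism <- sum(!eq[merged$start[j]:runs$end[i]])
      if (mism / cand_len <= max_mismatch_frac) {
        merged$end[j] <- runs$end[i]
      } else merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }
  runs
}

#' Find tandem-repeat arrays by period self-shift agreement
#'
#' For each candidate period `k`, positions where the sequence agrees with
#' itself shifted by `k` are collected into maximal runs; a run of
#' agreement length `L` spans an array of `L + k` bases and `(L + k)/k`
#' unit copies.  Overlapping detections at different periods are reduced
#' to the best period per locus (longest array; ties to the smallest
#' period).
#'
#' @param sequence character scalar.
#' @param min_period,max_period candidate period range (bp).
#' @param min_copies minimum unit copies.
#' @param max_mismatch_frac allowed fraction of self-shift disagreements
#'   within a run (0 = perfect arrays only).
#' @return data frame: `start`, `end`, `period`, `copies`,
#'   `consensus_unit`.
#' @export
find_tandem_arrays <- function(sequence, min_period = 1, max_period = 10,
                               min_copies = 3, max_mismatch_frac = 0) {
  if (min_period < 1 || max_period < min_period)
    stopf("need 1 <= min_period <= max_period")
  chars <- seq_chars(sequence)
  out <- list()
  for (k in min_period:max_period) {
    runs <- period_runs(chars, k, max_mismatch_frac)
    if (!nrow(runs)) next
    len <- runs$end - runs$start + 1L + k
    copies <- floor(len / k)
    keep <- copies >= min_copies
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      start = runs$start[keep], end = runs$end[keep] + k, period = k,
      copies = copies[keep],
      consensus_unit = substring(sequence, runs$start[keep],
                                 runs$start[keep] + k - 1L))
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), copies = integer(0),
                      consensus_unit = character(0)))
  arr <- do.call(rbind, out)
  # best period per locus: resolve only within connected overlap clusters
  # (a linear sweep; the pairwise rule is quadratic only locally)
  arr <- arr[order(arr$start, arr$end), , drop = FALSE]
  cl <- cumsum(c(1L, as.integer(arr$start[-1L] >
                                  cummax(arr$end)[-nrow(arr)])))
  keep <- rep(TRUE, nrow(arr))
  for (g in split(seq_len(nrow(arr)), cl)) {
    if (length(g) < 2L) next
    for (i in g) {
      if (!keep[i]) next
      for (j in g) {
        if (i == j || !keep[j]) next
        ov <- interval_overlap(arr$start[i], arr$end[i],
                               arr$start[j], arr$end[j])
        if (ov > 0.5 * min(arr$end[i] - arr$start[i] + 1L,
                           arr$end[j] - arr$start[j] + 1L)) {
          li <- arr$end[i] - arr$start[i] + 1L
          lj <- arr$end[j] - arr$start[j] + 1L
          # longer array wins; near-ties resolved to the smaller period
          drop_j <- lj < 0.9 * li || (li >= 0.9 * lj && lj >= 0.9 * li &&
                                        arr$period[j] > arr$period[i])
          if (drop_j) keep[j] <- FALSE else { keep[i] <- FALSE; break }
        }
      }
    }
  }
  arr <- arr[keep, , drop = FALSE]
  rownames(arr) <- NULL
  arr
}

#' Scan for pattern A: TSD embracing a TE and a captured gene fragment
#'
#' For every TE annotated within `max_gap` of a gene, searches for an exact
#' duplicated motif of at least `min_tsd` bp whose two copies flank the
#' combined TE-plus-gene block -- the signature of a DSB created by the TE
#' insertion and repaired with a fragment carrying the gene.
#'
#' @param sequence character scalar.
#' @param te_annotations,gene_annotations data frames with `start`, `end`
#'   and an id column (`feature_id`).
#' @param min_tsd minimum TSD length (bp); the default 8 keeps ordinary
#'   4--6 bp element TSDs from triggering the pattern.
#' @param max_gap maximum TE-gene gap (bp).
#' @param max_tsd maximum TSD length considered.
#' @return footprint data frame (possibly empty).
#' @export
scan_tsd_capture <- function(sequence, te_annotations, gene_annotations,
                             min_tsd = 8, max_gap = 2000, max_tsd = 30) {
  out <- footprint_df()
  if (!nrow(te_annotations) || !nrow(gene_annotations)) return(out)
  n <- nchar(sequence)
  for (i in seq_len(nrow(te_annotations))) {
    te <- te_annotations[i, ]
    for (j in seq_len(nrow(gene_annotations))) {
      g <- gene_annotations[j, ]
      gap <- max(te$start, g$start) - min(te$end, g$end) - 1L
      if (gap > max_gap) next
      bs <- min(te$start, g$start)
      be <- max(te$end, g$end)
      if (bs - 1L < min_tsd + 2L || n - be < min_tsd + 2L) next
      tsd <- detect_tsd(sequence, bs, be, min_len = min_tsd,
                        max_len = max_tsd, window = 2)
      if (is.null(tsd)) next
      out <- rbind(out, footprint_df("A_tsd_capture", tsd$left_start,
                                     tsd$right_end,
                                     gene_id = g$feature_id %||% NA_character_,
                                     partner_id = te$feature_id %||% NA_character_,
                                     evidence = tsd$sequence,
                                     score = tsd$length))
    }
  }
  unique(out)
}

#' Scan for pattern B: identical border shared by donor and acceptor
#'
#' Compares the flanks of a moved gene copy (acceptor) and its paralog
#' (donor): on each side, the longest exact common terminal motif anchored
#' at the gene boundary is measured; a motif of at least `min_border` bp on
#' either side is reported.
#'
#' @param acceptor_sequence,donor_sequence character scalars.
#' @param acceptor_interval,donor_interval `c(start, end)` gene intervals.
#' @param min_border minimum shared border length (bp); default 6.
#' @param max_flank flank length examined (bp).
#' @return one footprint row, or `NULL` when no border qualifies.
#' @export
scan_shared_border <- function(acceptor_sequence, acceptor_interval,
                               donor_sequence, donor_interval,
                               min_border = 6, max_flank = 200) {
  af <- flanks(acceptor_sequence, acceptor_interval, max_flank)
  df <- flanks(donor_sequence, donor_interval, max_flank)
  if (!nzchar(af$left) || !nzchar(af$right) || !nzchar(df$left) ||
      !nzchar(df$right))
    stopf("insufficient flank around a gene interval")
  left_len <- common_suffix_len(af$left, df$left)
  right_len <- common_prefix_len(af$right, df$right)
  best <- max(left_len, right_len)
  if (best < min_border) return(NULL)
  side <- if (right_len >= left_len) "right" else "left"
  motif <- if (side == "right") substr(af$right, 1L, right_len)
           else substr(af$left, nchar(af$left) - left_len + 1L, nchar(af$left))
  st <- if (side == "right") acceptor_interval[2] + 1L
        else acceptor_interval[1] - best
  footprint_df("B_shared_border", st, st + best - 1L,
               evidence = motif, score = best)
}

flanks <- function(sequence, interval, max_flank) {
  n <- nchar(sequence)
  list(left = substr(sequence, max(1L, interval[1] - max_flank),
                     interval[1] - 1L),
       right = substr(sequence, interval[2] + 1L,
                      min(n, interval[2] + max_flank)))
}

common_prefix_len <- function(a, b) {
  m <- min(nchar(a), nchar(b))
  if (m == 0L) return(0L)
  ac <- seq_chars(substr(a, 1L, m)); bc <- seq_chars(substr(b, 1L, m))
  d <- which(ac != bc)
  if (!length(d)) m else d[1L] - 1L
}

common_suffix_len <- function(a, b) {
  m <- min(nchar(a), nchar(b))
  if (m == 0L) return(0L)
  ac <- rev(seq_chars(substr(a, nchar(a) - m + 1L, nchar(a))))
  bc <- rev(seq_chars(substr(b, nchar(b) - m + 1L, nchar(b))))
  d <- which(ac != bc)
  if (!length(d)) m else d[1L] - 1L
}

#' Scan for pattern C: genes captured inside Helitron elements
#'
#' @param te_annotations data frame with `start`, `end`, `class`,
#'   `feature_id`.
#' @param gene_annotations data frame with `start`, `end`, `feature_id`.
#' @return footprint rows for genes fully contained in a Helitron-class
#'   element.
#' @export
scan_helitron_capture <- function(te_annotations, gene_annotations) {
  out <- footprint_df()
  hel <- te_annotations[te_annotations$class %in% "Helitron", , drop = FALSE]
  if (!nrow(hel) || !nrow(gene_annotations)) return(out)
  for (i in seq_len(nrow(hel))) {
    inside <- gene_annotations$start >= hel$start[i] &
      gene_annotations$end <= hel$end[i]
    for (j in which(inside))
      out <- rbind(out, footprint_df(
        "C_helitron_capture", gene_annotations$start[j],
        gene_annotations$end[j],
        gene_id = gene_annotations$feature_id[j] %||% NA_character_,
        partner_id = hel$feature_id[i] %||% NA_character_,
        evidence = NA_character_, score = 0L))
  }
  out
}

#' Scan for pattern D: genes flanked by tandem arrays on both sides
#'
#' @param gene_annotations data frame with `start`, `end`, `feature_id`.
#' @param arrays data frame from [find_tandem_arrays()].
#' @param window maximum distance (bp) from gene boundary to array.
#' @return footprint rows; evidence holds both array units.
#' @export
scan_tandem_flank <- function(gene_annotations, arrays, window = 500) {
  out <- footprint_df()
  if (!nrow(gene_annotations) || !nrow(arrays)) return(out)
  for (j in seq_len(nrow(gene_annotations))) {
    g <- gene_annotations[j, ]
    # an array qualifies when it lies on the correct side and reaches to
    # within `window` bp of the gene boundary (detected array edges may
    # slip a base or two across the boundary by chance agreement)
    left <- arrays[arrays$start < g$start &
                     arrays$end >= g$start - window - 1L, , drop = FALSE]
    right <- arrays[arrays$end > g$end &
                      arrays$start <= g$end + window + 1L, , drop = FALSE]
    if (nrow(left) && nrow(right)) {
      la <- left[which.max(left$end), ]
      ra <- right[which.min(right$start), ]
      out <- rbind(out, footprint_df(
        "D_tandem_flank", la$start, ra$end,
        gene_id = g$feature_id %||% NA_character_,
        evidence = paste(la$consensus_unit, ra$consensus_unit, sep = "|"),
        score = as.integer(la$end - la$start + 1L + ra$end - ra$start + 1L)))
    }
  }
  out
}

#' Flag retrocopies among paralogous gene pairs
#'
#' A pair is flagged when one member has two or more exons, the other
#' exactly one, and the single exon's length is within 10 percent of the
#' partner's summed exon length -- the signature of reinsertion of a
#' reverse-transcribed processed mRNA.
#'
#' @param genes data frame with `feature_id`, `n_exons`, `exon_bp`,
#'   `start`, `end`.
#' @param homology_pairs data frame with columns `id1`, `id2`.
#' @param tolerance relative exon-length tolerance.
#' @return footprint rows (pattern E).
#' @export
flag_retrocopy <- function(genes, homology_pairs, tolerance = 0.1) {
  out <- footprint_df()
  if (!nrow(homology_pairs)) return(out)
  for (i in seq_len(nrow(homology_pairs))) {
    g1 <- genes[genes$feature_id == homology_pairs$id1[i], ]
    g2 <- genes[genes$feature_id == homology_pairs$id2[i], ]
    if (nrow(g1) != 1L || nrow(g2) != 1L) next
    if (g1$n_exons >= 2L && g2$n_exons == 1L) { multi <- g1; single <- g2 }
    else if (g2$n_exons >= 2L && g1$n_exons == 1L) { multi <- g2; single <- g1 }
    else next
    if (abs(single$exon_bp - multi$exon_bp) <= tolerance * multi$exon_bp)
      out <- rbind(out, footprint_df(
        "E_retrocopy", single$start, single$end,
        gene_id = single$feature_id, partner_id = multi$feature_id,
        evidence = sprintf("exons:%d~%d;bp:%d~%d", single$n_exons,
                           multi$n_exons, single$exon_bp, multi$exon_bp),
        score = as.integer(single$exon_bp)))
  }
  out
}

#' Exon summary of genes in a truth table
#'
#' @param truth truth data frame from [simulate_region()].
#' @return data frame: `feature_id`, `start`, `end`, `n_exons`, `exon_bp`.
#' @export
truth_gene_summary <- function(truth) {
  genes <- truth[truth$kind == "gene", , drop = FALSE]
  exons <- truth[truth$kind == "part" & truth$role %in% "exon", , drop = FALSE]
  if (!nrow(genes))
    return(data.frame(feature_id = character(0), start = integer(0),
                      end = integer(0), n_exons = integer(0),
                      exon_bp = integer(0)))
  n_ex <- vapply(genes$feature_id, function(id)
    sum(exons$parent == id), integer(1))
  bp <- vapply(genes$feature_id, function(id) {
    e <- exons[exons$parent == id, ]
    as.integer(sum(e$end - e$start + 1L))
  }, integer(1))
  data.frame(feature_id = genes$feature_id, start = genes$start,
             end = genes$end, n_exons = unname(n_ex), exon_bp = unname(bp),
             stringsAsFactors = FALSE)
}
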