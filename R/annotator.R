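# Structural LTR annotation: candidate LTR pairs by self-comparison,
# consensus-library matching for solo/truncated remnants, target-site
# duplication detection, and assembly into annotated elements.

#' Find candidate LTR pairs by sequence self-comparison
#'
#' Seeds the sequence against itself with exact k-mers (forward strand: the
#' two LTRs of one element are co-oriented), chains co-diagonal seeds and
#' extends each chain without gaps under an X-drop rule.  Candidates must
#' satisfy the LTR-length, span and identity bounds; overlapping candidates
#' are resolved longest-outer-span-first.
#'
#' @param sequence character scalar.
#' @param min_ltr,max_ltr allowed LTR length range (bp).
#' @param min_span,max_span allowed outer span (5' LTR start to 3' LTR end).
#' @param min_identity minimum LTR-LTR identity.
#' @param seed_k exact seed length.
#' @param xdrop extension drop-off score.
#' @param chain_gap maximum gap between co-diagonal seeds in one chain.
#' @param max_occ k-mers occurring more often than this are skipped
#'   (low-complexity guard).
#' @param resolve `"span"` resolves overlapping candidates
#'   longest-outer-span-first; `"none"` returns all candidates so a later
#'   stage (see [assemble_elements()]) can resolve conflicts jointly with
#'   homology evidence.
#' @return data frame of candidates: `left_start`, `left_end`,
#'   `right_start`, `right_end`, `ltr_len`, `span`, `identity`, sorted by
#'   position then descending identity.
#' @export
find_ltr_pairs <- function(sequence, min_ltr = 100, max_ltr = 3000,
                           min_span = 1000, max_span = 18000,
                           min_identity = 0.80, seed_k = 20, xdrop = 15,
                           chain_gap = 60, max_occ = 50,
                           resolve = c("span", "none")) {
  resolve <- match.arg(resolve)
  empty <- data.frame(left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      ltr_len = integer(0), span = integer(0),
                      identity = numeric(0))
  if (!nzchar(sequence %||% "")) return(empty)
  if (min_ltr < seed_k) stopf("min_ltr must be >= seed_k")
  if (min_span <= 2 * min_ltr) stopf("min_span must exceed 2*min_ltr")
  if (max_ltr < min_ltr || max_span < min_span || min_identity <= 0 ||
      min_identity > 1)
    stopf("invalid search bounds")
  n <- nchar(sequence)
  km <- kmer_starts(sequence, seed_k)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  dup[grepl("[^ACGT]", km)] <- FALSE
  if (!any(dup)) return(empty)
  groups <- split(which(dup), km[dup])
  d_lo <- max(min_ltr, min_span - max_ltr)
  seeds_i <- integer(0); seeds_d <- integer(0)
  for (g in groups) {
    m <- length(g)
    if (m > max_occ) next
    for (a in seq_len(m - 1L)) {
      d <- g[(a + 1L):m] - g[a]
      ok <- d >= d_lo & d <= max_span
      if (any(ok)) {
        seeds_i <- c(seeds_i, rep(g[a], sum(ok)))
        seeds_d <- c(seeds_d, d[ok])
      }
    }
  }
  if (!length(seeds_i)) return(empty)
  chars <- seq_chars(sequence)
  cand <- list()
  for (d in unique(seeds_d)) {
    for (run in run_groups(seeds_i[seeds_d == d], chain_gap)) {
      c_start <- run[1L]; c_end <- run[length(run)] + seed_k - 1L
      lo <- max(1L, c_start - max_ltr)
      # left copy may not run into the right copy, nor off the sequence
      hi <- min(c_start + d - 1L - 1L, n - d, c_end + max_ltr)
      if (hi < c_end) next
      ext <- extend_chain(chars, chars, d, c_start, c_end, lo, hi, xdrop)
      cand[[length(cand) + 1L]] <- c(ext[1L], ext[2L], d, ext[3L])
    }
  }
  if (!length(cand)) return(empty)
  df <- as.data.frame(do.call(rbind, cand))
  names(df) <- c("start", "end", "d", "matches")
  df <- merge_same_diagonal(df)
  len <- df$end - df$start + 1L
  out <- data.frame(left_start = df$start, left_end = df$end,
                    right_start = df$start + df$d, right_end = df$end + df$d,
                    ltr_len = len, span = df$end + df$d - df$start + 1L,
                    identity = df$matches / len)
  out <- out[out$ltr_len >= min_ltr & out$ltr_len <= max_ltr &
               out$span >= min_span & out$span <= max_span &
               out$identity >= min_identity &
               out$left_end < out$right_start, , drop = FALSE]
  if (!nrow(out)) return(empty)
  if (resolve == "span")
    out <- resolve_pair_conflicts(out[order(-out$span, out$left_start), ])
  out <- out[order(out$left_start, -out$identity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# greedy acceptance in the given priority order; two candidates conflict
# when they claim substantially the same bases as an LTR (nested elements
# survive: a guest's LTRs fall inside the host's inter-LTR region)
resolve_pair_conflicts <- function(out) {
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    conflict <- FALSE
    for (j in which(keep)) {
      ov <- max(interval_overlap(out$left_start[i], out$left_end[i],
                                 out$left_start[j], out$left_end[j]),
                interval_overlap(out$left_start[i], out$left_end[i],
                                 out$right_start[j], out$right_end[j]),
                interval_overlap(out$right_start[i], out$right_end[i],
                                 out$left_start[j], out$left_end[j]),
                interval_overlap(out$right_start[i], out$right_end[i],
                                 out$right_start[j], out$right_end[j]))
      if (ov > 0.5 * min(out$ltr_len[i], out$ltr_len[j])) {
        conflict <- TRUE
        break
      }
    }
    keep[i] <- !conflict
  }
  out[keep, , drop = FALSE]
}

#' Match a repeat library against a sequence
#'
#' Ungapped seed-and-extend local matching of every library consensus
#' against both strands of the sequence.  Hits below the identity or
#' consensus-coverage thresholds are dropped; overlapping hits are resolved
#' best-identity-first.
#'
#' @param sequence character scalar.
#' @param library a `repeat_library`.
#' @param min_identity minimum alignment identity.
#' @param min_cov minimum aligned fraction of the consensus.
#' @param seed_k exact seed length.
#' @param xdrop extension drop-off score.
#' @param chain_gap maximum within-chain seed gap.
#' @return data frame: `family`, `class`, `role`, `start`, `end`, `strand`,
#'   `identity`, `coverage`, `qstart`, `qend`, `qlen`.
#' @export
match_library <- function(sequence, library, min_identity = 0.80,
                          min_cov = 0.10, seed_k = 12, xdrop = 15,
                          chain_gap = 120) {
  stopifnot(inherits(library, "repeat_library"))
  empty <- data.frame(family = character(0), class = character(0),
                      role = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      qstart = integer(0), qend = integer(0),
                      qlen = integer(0))
  n <- nchar(sequence)
  if (n < seed_k) return(empty)
  skm <- kmer_starts(sequence, seed_k)
  smap <- split(seq_along(skm), skm)
  chars <- seq_chars(sequence)
  hits <- list()
  for (i in seq_len(nrow(library))) {
    qlen <- nchar(library$sequence[i])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") library$sequence[i]
           else seq_rc(library$sequence[i])
      qk <- kmer_starts(q, seed_k)
      pos_list <- smap[qk]
      found <- which(!vapply(pos_list, is.null, logical(1)))
      if (!length(found)) next
      qpos <- rep(found, lengths(pos_list[found]))
      spos <- unlist(pos_list[found], use.names = FALSE)
      d <- spos - qpos
      qchars <- seq_chars(q)
      ext_rows <- list()
      for (dd in unique(d)) {
        for (run in run_groups(spos[d == dd], chain_gap)) {
          c_start <- run[1L]; c_end <- run[length(run)] + seed_k - 1L
          lo <- max(1L, dd + 1L)            # query coordinate >= 1
          hi <- min(n, dd + qlen)           # query coordinate <= qlen
          # compare subject position p to query position p - dd
          ext <- extend_chain(chars, c(rep("!", 0), qchars), -dd,
                              c_start, c_end, lo, hi, xdrop)
          ext_rows[[length(ext_rows) + 1L]] <- c(ext[1L], ext[2L], dd, ext[3L])
        }
      }
      if (!length(ext_rows)) next
      df <- as.data.frame(do.call(rbind, ext_rows))
      names(df) <- c("start", "end", "d", "matches")
      df <- merge_same_diagonal(df)
      len <- df$end - df$start + 1L
      qs <- df$start - df$d; qe <- df$end - df$d
      if (strand == "-") {
        tmp <- qs
        qs <- qlen - qe + 1L
        qe <- qlen - tmp + 1L
      }
      h <- data.frame(family = library$family[i], class = library$class[i],
                      role = library$role[i], start = df$start, end = df$end,
                      strand = strand, identity = df$matches / len,
                      coverage = len / qlen, qstart = qs, qend = qe,
                      qlen = qlen)
      h <- h[h$identity >= min_identity & h$coverage >= min_cov &
               (h$end - h$start + 1L) >= 2L * seed_k, , drop = FALSE]
      if (nrow(h)) hits[[length(hits) + 1L]] <- h
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  # best-identity-first resolution of conflicting (substantially
  # overlapping) hits
  out <- out[order(-out$identity, -(out$end - out$start)), ]
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    conflict <- FALSE
    for (j in which(keep)) {
      ov <- interval_overlap(out$start[i], out$end[i], out$start[j], out$end[j])
      if (ov > 0.5 * min(out$end[i] - out$start[i] + 1L,
                         out$end[j] - out$start[j] + 1L)) {
        conflict <- TRUE
        break
      }
    }
    keep[i] <- !conflict
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect a target-site duplication around an element
#'
#' Finds the longest pair of identical substrings with one copy ending
#' within `window` bp of the element's left boundary and the other starting
#' within `window` bp of its right boundary (the small symmetric window
#' absorbs 1--2 bp boundary slop from the annotator).  Ties are broken by
#' proximity to the boundary, then leftmost.
#'
#' @param sequence character scalar.
#' @param element_start,element_end 1-based inclusive element interval.
#' @param min_len,max_len accepted TSD length range (bp).
#' @param window boundary tolerance (bp).
#' @return a list (`sequence`, `length`, `left_start`, `left_end`,
#'   `right_start`, `right_end`) or `NULL` when no TSD qualifies.
#' @export
detect_tsd <- function(sequence, element_start, element_end, min_len = 4,
                       max_len = 20, window = 2) {
  n <- nchar(sequence)
  stopifnot(element_start >= 1, element_end <= n,
            element_start <= element_end)
  if (element_start - 1L < min_len + window || n - element_end < min_len + window)
    stopf("insufficient flank for TSD detection")
  offs <- expand.grid(oL = -window:window, oR = -window:window)
  offs <- offs[order(abs(offs$oL) + abs(offs$oR), offs$oL, offs$oR), ]
  for (len in seq(min(max_len, element_start - 1L - (-window),
                      n - element_end + window), min_len)) {
    for (r in seq_len(nrow(offs))) {
      le <- element_start - 1L + offs$oL[r]   # left copy end
      rs <- element_end + 1L + offs$oR[r]     # right copy start
      ls <- le - len + 1L
      re <- rs + len - 1L
      if (ls < 1L || re > n || le >= element_start + window || rs <= le) next
      a <- substr(sequence, ls, le)
      if (a == substr(sequence, rs, re))
        return(list(sequence = a, length = len, left_start = ls,
                    left_end = le, right_start = rs, right_end = re))
    }
  }
  NULL
}
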