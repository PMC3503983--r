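# Exact k-mer seeding, co-diagonal chaining and ungapped X-drop extension.
#
# Both alignment stages of the annotator are ungapped: the simulator plants
# no indels inside repeats, and on real data this is documented as a
# contract (indel-rich alignments need a gapped aligner).  A chain lives on
# one diagonal; extension compares characters at a fixed offset and keeps
# the maximum-scoring endpoint (+1 match / -1 mismatch, stop when the score
# falls `xdrop` below the running maximum).

kmer_starts <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# maximal runs of sorted integer positions with successive gaps <= gap
run_groups <- function(pos, gap) {
  if (!length(pos)) return(list())
  pos <- sort(pos)
  brk <- c(0L, which(diff(pos) > gap), length(pos))
  lapply(seq_len(length(brk) - 1L),
         function(i) pos[(brk[i] + 1L):brk[i + 1L]])
}

# X-drop scan over a logical match vector (ordered outward from the chain
# edge); returns how many positions to extend.
xdrop_best <- function(m, xdrop) {
  if (!length(m)) return(0L)
  sc <- cumsum(ifelse(m, 1L, -1L))
  cm <- cummax(sc)
  viol <- which(sc < cm - xdrop)
  lim <- if (length(viol)) viol[1L] - 1L else length(sc)
  if (lim == 0L) return(0L)
  best <- which.max(sc[seq_len(lim)])
  if (sc[best] <= 0L) 0L else best
}

# Extend one chain on diagonal d of a self-comparison (subject vs itself) or
# of query-vs-subject where `bchars` differs.  `lo`/`hi` bound the left-copy
# coordinate.  Returns c(start, end, matches) of the left-copy interval.
extend_chain <- function(achars, bchars, d, c_start, c_end, lo, hi, xdrop) {
  # left
  if (c_start > lo) {
    p <- (c_start - 1L):lo
    m <- achars[p] == bchars[p + d]
    c_start <- c_start - xdrop_best(m, xdrop)
  }
  if (c_end < hi) {
    p <- (c_end + 1L):hi
    m <- achars[p] == bchars[p + d]
    c_end <- c_end + xdrop_best(m, xdrop)
  }
  iv <- c_start:c_end
  c(c_start, c_end, sum(achars[iv] == bchars[iv + d]))
}

# deduplicate/merge extended chains that landed on the same interval of the
# same diagonal; keeps the best-scoring representative among overlaps
merge_same_diagonal <- function(df) {
  if (nrow(df) < 2L) return(df)
  keep <- rep(TRUE, nrow(df))
  df <- df[order(-df$matches), ]
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(df))) {
      if (j == i || !keep[j]) next
      if (df$d[i] == df$d[j] &&
          interval_overlap(df$start[i], df$end[i], df$start[j], df$end[j]) > 0)
        keep[j] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}
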