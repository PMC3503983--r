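#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so package internals can
#' consume deterministic random streams without disturbing the caller's RNG.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic stream derivation: one master seed, one sub-stream per named
# feature, so adding a feature never perturbs the streams of earlier ones.
hash_key <- function(key) {
  h <- 0
  for (c in utf8ToInt(as.character(key))) h <- (h * 31 + c) %% 2147483647
  h
}

derive_seed <- function(master, key) {
  as.integer((as.double(master) * 48271 + hash_key(key) + 1) %% 2147483647)
}

# sequences are plain upper-case character scalars internally
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste0(x, collapse = "")

seq_rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

random_dna_chars <- function(n, gc_fraction = 0.5) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                  gc_fraction / 2, (1 - gc_fraction) / 2))
}

gc_content <- function(s) {
  x <- seq_chars(s)
  sum(x %in% c("G", "C")) / length(x)
}

# overlap width of two 1-based closed intervals (0 if disjoint)
interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}
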