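# Shared fixture builders and independent oracles.

# a mixed-fate region: n elements cycling through all nine fates, ages
# cycling 0.5/1/2 My unless fixed
fate_region <- function(seed, n_elements = 27, ages = c(5e5, 1e6, 2e6),
                        region_length = 1.2e5) {
  fates <- fate_categories()
  cfg <- sim_config(
    region_length = region_length, seed = seed,
    elements = lapply(seq_len(n_elements), function(i)
      plant_spec(age_years = ages[(i %% length(ages)) + 1],
                 fate = fates[(i %% 9) + 1])))
  simulate_region(cfg)
}

# reciprocal-overlap (>= frac) match of called intervals against one truth
# interval; returns index of the unique match or integer(0)
match_interval <- function(called_start, called_end, ts, te, frac = 0.9) {
  ov <- pmin(called_end, te) - pmax(called_start, ts) + 1
  which(ov >= frac * pmax(called_end - called_start + 1, te - ts + 1))
}

# fraction of planted elements recovered with the correct fate
fate_recovery <- function(region) {
  el <- annotate_region(region$sequence, region$library)
  fates <- classify_fates(el, region$library, region$sequence)
  tr <- region$truth[region$truth$kind == "ltr_element", ]
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    j <- match_interval(fates$start, fates$end, tr$start[i], tr$end[i])
    length(j) == 1 && fates$category[j] == tr$fate[i]
  }, logical(1))
  list(ok = sum(hit), total = nrow(tr), truth = tr, fates = fates)
}

# sensitivity/precision of annotated element intervals against truth
annotation_accuracy <- function(region) {
  el <- as.data.frame(annotate_region(region$sequence, region$library))
  tr <- region$truth[region$truth$kind == "ltr_element", ]
  sens <- mean(vapply(seq_len(nrow(tr)), function(i)
    length(match_interval(el$start, el$end, tr$start[i], tr$end[i])) == 1,
    logical(1)))
  prec <- mean(vapply(seq_len(nrow(el)), function(i)
    length(match_interval(tr$start, tr$end, el$start[i], el$end[i])) == 1,
    logical(1)))
  list(sensitivity = sens, precision = prec, n_truth = nrow(tr),
       n_called = nrow(el))
}

# ---- independent oracles ---------------------------------------------------

# brute-force TSD oracle: enumerate every (left end, right start, length)
# combination allowed by the contract, then select by length desc,
# boundary proximity, leftmost
oracle_tsd <- function(sequence, s, e, min_len, max_len, window) {
  n <- nchar(sequence)
  cands <- list()
  for (oL in -window:window) for (oR in -window:window) {
    le <- s - 1 + oL
    rs <- e + 1 + oR
    for (len in min_len:max_len) {
      ls <- le - len + 1
      re <- rs + len - 1
      if (ls < 1 || re > n || rs <= le) next
      if (substr(sequence, ls, le) == substr(sequence, rs, re))
        cands[[length(cands) + 1]] <-
          data.frame(len = len, prox = abs(oL) + abs(oR), oL = oL, oR = oR,
                     ls = ls, le = le, rs = rs, re = re)
    }
  }
  if (!length(cands)) return(NULL)
  d <- do.call(rbind, cands)
  d <- d[order(-d$len, d$prox, d$oL, d$oR), ]
  as.list(d[1, ])
}

# quadratic-space Gotoh global aligner returning the optimal score under
# match +1 / mismatch -1 / gap opening -5 / gap extension -1 per position
# (a gap of length L costs 5 + L)
oracle_align_score <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  go <- 5; ge <- 1
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- -go - ge * (j - 1)
  for (i in 2:(n + 1)) X[i, 1] <- -go - ge * (i - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sub <- if (A[i - 1] == B[j - 1]) 1 else -1
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sub
    X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
    Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# naive per-position tandem-run scanner for one period
oracle_period_runs <- function(sequence, k) {
  x <- strsplit(sequence, "")[[1]]
  n <- length(x)
  runs <- data.frame(start = integer(0), end = integer(0))
  if (n < 2 * k) return(runs)
  i <- 1
  while (i <= n - k) {
    if (x[i] == x[i + k]) {
      j <- i
      while (j + 1 <= n - k && x[j + 1] == x[j + 1 + k]) j <- j + 1
      runs <- rbind(runs, data.frame(start = i, end = j))
      i <- j + 1
    }
    i <- i + 1
  }
  runs
}
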