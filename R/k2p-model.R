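# Kimura two-parameter substitution process.
#
# Parameterised by the overall substitution rate r (substitutions per site
# per year, the sum of the transition rate and both transversion rates) and
# kappa, the transition/transversion *rate* ratio alpha/beta.  Under K2P a
# site leaves at rate alpha to its transition partner and at rate beta to
# each of the two transversion states, so r = alpha + 2*beta.

k2p_rate_components <- function(r, kappa) {
  if (!is_scalar_number(r) || r <= 0) stopf("substitution rate r must be > 0")
  if (!is_scalar_number(kappa) || kappa <= 0) stopf("kappa must be > 0")
  beta <- r / (kappa + 2)
  list(alpha = kappa * beta, beta = beta)
}

# Closed-form site substitution probabilities after time t on one lineage.
k2p_site_probs <- function(t, r, kappa) {
  rc <- k2p_rate_components(r, kappa)
  p_ti <- 0.25 + 0.25 * exp(-4 * rc$beta * t) -
    0.5 * exp(-2 * (rc$alpha + rc$beta) * t)
  p_tv <- 0.25 - 0.25 * exp(-4 * rc$beta * t) # each of the two targets
  list(p_ti = p_ti, p_tv = p_tv)
}

#' Expected raw divergence between two sequence copies under K2P
#'
#' Closed-form expected proportion of mismatching sites between two copies
#' that have evolved independently for `age_years` each (total path length
#' `2 * age_years`) at overall rate `r` with transition/transversion rate
#' ratio `kappa`.
#'
#' @param age_years age of the duplication in years.
#' @param r substitution rate in substitutions per site per year.
#' @param kappa transition/transversion rate ratio.
#' @return expected mismatch proportion in `[0, 0.75)`.
#' @export
expected_ltr_divergence <- function(age_years, r = 1.3e-8, kappa = 2) {
  p <- k2p_site_probs(2 * age_years, r, kappa)
  p$p_ti + 2 * p$p_tv
}

TI_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_ONE     <- c(A = "C", G = "C", C = "A", T = "A")
TV_TWO     <- c(A = "T", G = "T", C = "G", T = "G")

# Evolve a character vector of bases for time t under K2P.  Non-ACGT
# characters are left untouched.  Consumes the current RNG stream.
evolve_k2p <- function(x, t, r, kappa) {
  if (t == 0) return(x)
  p <- k2p_site_probs(t, r, kappa)
  n <- length(x)
  u <- runif(n)
  acgt <- x %in% c("A", "C", "G", "T")
  ti <- acgt & u < p$p_ti
  tv <- acgt & !ti & u < p$p_ti + 2 * p$p_tv
  if (any(ti)) x[ti] <- TI_PARTNER[x[ti]]
  if (any(tv)) {
    pick <- runif(sum(tv)) < 0.5
    x[tv] <- ifelse(pick, TV_ONE[x[tv]], TV_TWO[x[tv]])
  }
  x
}

# Transition / transversion classification of aligned base pairs.
is_transition_pair <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}
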