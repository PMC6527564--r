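#' Unit-square sigmoid choice probability
#'
#' Maps a prediction `muhat1` to the probability of choosing the association
#' (`y = 1`) through the unit-square sigmoid
#' `muhat1^zeta / (muhat1^zeta + (1 - muhat1)^zeta)`, computed in the
#' equivalent stable form `plogis(zeta * qlogis(muhat1))`. `zeta` is the
#' inverse decision noise: `zeta = 1` is probability matching, and as
#' `zeta -> Inf` the choice becomes a hard threshold at 0.5.
#'
#' @param muhat1 Prediction, strictly inside (0, 1); vectorised.
#' @param zeta Inverse decision noise, > 0.
#' @return Choice probability in (0, 1).
#' @export
#' @examples
#' choice_probability(0.8, 2)   # 0.64 / 0.68
choice_probability <- function(muhat1, zeta) {
  abort_if(!is.finite(zeta) || zeta <= 0, "zeta must be > 0")
  abort_if(any(muhat1 <= 0 | muhat1 >= 1),
           "muhat1 must lie strictly inside (0, 1)")
  stats::plogis(zeta * stats::qlogis(muhat1))
}

#' Sample binary choices
#'
#' Bernoulli draw(s) from the current RNG stream; seed management is the
#' caller's responsibility (see [derive_seed()]).
#'
#' @param p Choice probability (vectorised), in `[0, 1]`.
#' @return Integer 0/1 vector of `length(p)`.
#' @export
simulate_choice <- function(p) {
  abort_if(any(p < 0 | p > 1 | !is.finite(p)), "p must lie in [0, 1]")
  as.integer(stats::runif(length(p)) < p)
}

#' Bernoulli log-likelihood of a choice sequence
#'
#' `sum(y * log(p) + (1 - y) * log(1 - p))` with probabilities clipped to
#' `[1e-12, 1 - 1e-12]` to guard saturated predictions; the number of
#' clipped entries is attached as attribute `n_clipped`.
#'
#' @param y Binary choice sequence.
#' @param p Choice probability sequence, same length.
#' @return Log-likelihood (<= 0) with attribute `n_clipped`.
#' @export
log_likelihood <- function(y, p) {
  abort_if(length(y) != length(p), "y and p must have equal length")
  eps <- 1e-12
  n_clipped <- sum(p < eps | p > 1 - eps)
  p <- pmin(pmax(p, eps), 1 - eps)
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  attr(ll, "n_clipped") <- n_clipped
  ll
}
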