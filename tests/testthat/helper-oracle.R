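# Independent straight-line transcription of the three-level binary HGF(-S)
# update equations, used as a dual-implementation oracle. Deliberately kept
# separate from the package internals: the level-1 posterior is computed from
# the two Gaussian densities directly, and every update is written out
# formula by formula.
oracle_hgfs_filter <- function(u, noise, omega2, omega3, tau, kappa = 1,
                               mu2_0 = 0, sigma2_0 = 0.1,
                               mu3_0 = 1, sigma3_0 = 1) {
  n <- length(u)
  res <- data.frame(muhat1 = numeric(n), mu1 = numeric(n),
                    delta1 = numeric(n), mu2 = numeric(n),
                    sigma2 = numeric(n), mu3 = numeric(n),
                    sigma3 = numeric(n), delta2 = numeric(n))
  mu2 <- mu2_0; sigma2 <- sigma2_0; mu3 <- mu3_0; sigma3 <- sigma3_0
  for (k in seq_len(n)) {
    muhat1 <- 1 / (1 + exp(-mu2))
    pihat2 <- 1 / (sigma2 + exp(kappa * mu3 + omega2))
    pihat3 <- 1 / (sigma3 + exp(omega3))
    if (noise[k]) {
      sdv <- sqrt(exp(tau) / 2)
      num <- stats::dnorm(u[k], 1, sdv) * muhat1
      den <- num + stats::dnorm(u[k], 0, sdv) * (1 - muhat1)
      mu1 <- num / den
    } else {
      mu1 <- u[k]
    }
    delta1 <- mu1 - muhat1
    pi2 <- pihat2 + muhat1 * (1 - muhat1)
    sigma2_new <- 1 / pi2
    mu2_new <- mu2 + sigma2_new * delta1
    delta2 <- (sigma2_new + (mu2_new - mu2)^2) /
      (sigma2 + exp(kappa * mu3 + omega2)) - 1
    w2 <- exp(kappa * mu3 + omega2) * pihat2
    pi3 <- pihat3 + (kappa^2 / 2) * w2 * (w2 + (2 * w2 - 1) * delta2)
    sigma3 <- 1 / pi3
    mu3 <- mu3 + sigma3 * (kappa / 2) * w2 * delta2
    mu2 <- mu2_new; sigma2 <- sigma2_new
    res[k, ] <- c(muhat1, mu1, delta1, mu2, sigma2, mu3, sigma3, delta2)
  }
  res
}

# Fixed 20-trial input sequence and congruency flags used by the reduction
# and dual-implementation checks.
fixture_20 <- function() {
  list(
    u = c(1, 1, 0, 1, 1, 1, 0, 0, 1, 1, 0, 1, 0, 0, 1, 1, 1, 0, 1, 0),
    congruent = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE,
                  TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE,
                  TRUE, TRUE, FALSE, TRUE)
  )
}

fixture_20_data <- function() {
  fx <- fixture_20()
  tibble::tibble(u = fx$u, congruent = fx$congruent)
}

# Build a per-trial dataset for decision-change tests from a list of
# (correct, congruent, changed) pair descriptions: trial k carries the k-th
# description and y flips between k and k+1 iff changed[k].
make_dc_data <- function(correct, congruent, changed, label) {
  n <- length(changed) + 1
  y <- integer(n)
  y[1] <- 0L
  for (k in seq_len(n - 1)) y[k + 1] <- if (changed[k]) 1L - y[k] else y[k]
  tibble::tibble(
    y = y,
    correct = c(correct, TRUE),
    congruent = c(congruent, TRUE),
    uncertainty_label = c(label, "high")
  )
}
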