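#' Filter a trial sequence through the Rescorla-Wagner model
#'
#' Delta-rule value learning with a fixed learning rate:
#' `v^(k) = v^(k-1) + alpha * (u^(k) - v^(k-1))`. The prediction used by the
#' response model on trial `k` is the pre-update value `v^(k-1)`.
#'
#' @param data A data frame with binary input column `u`.
#' @param alpha Learning rate, strictly inside (0, 1).
#' @param v0 Initial value, default 0.5.
#' @return A tibble of class `rw_trajectory` with columns `trial`, `muhat1`
#'   (the prediction `v^(k-1)`), `value` (`v^(k)`), `delta1`.
#' @export
filter_rw <- function(data, alpha, v0 = 0.5) {
  require_columns(data, "u", "data")
  abort_if(!is.finite(alpha) || alpha <= 0 || alpha >= 1,
           "alpha must lie strictly inside (0, 1)")
  n <- nrow(data)
  abort_if(n == 0, "data must contain at least one trial")
  v <- numeric(n)
  muhat <- numeric(n)
  prev <- v0
  for (k in seq_len(n)) {
    muhat[k] <- prev
    prev <- prev + alpha * (data$u[k] - prev)
    v[k] <- prev
  }
  traj <- tibble::tibble(trial = seq_len(n), muhat1 = muhat, value = v,
                         delta1 = data$u - muhat)
  structure(traj, class = c("rw_trajectory", class(traj)),
            params = list(alpha = alpha, v0 = v0))
}

#' Filter a trial sequence through the Sutton K1 model
#'
#' Delta-rule learning with a per-trial adaptive gain (Sutton's K1 scheme,
#' restricted to gains in (0, 1) via a logistic squash). The log-gain
#' `beta^(k)` moves with the correlation between the current prediction
#' error and an eligibility trace `h` of recent updates:
#' \preformatted{
#'   delta^(k) = u^(k) - v^(k-1)
#'   beta^(k)  = beta^(k-1) + mu_meta * delta^(k) * h^(k-1)
#'   alpha^(k) = logistic(beta^(k))
#'   v^(k)     = v^(k-1) + alpha^(k) * delta^(k)
#'   h^(k)     = h^(k-1) * max(0, 1 - alpha^(k)) + alpha^(k) * delta^(k)
#' }
#' Consistent runs of same-signed errors grow the gain; decorrelated errors
#' shrink it. With `mu_meta = 0` the model reduces to Rescorla-Wagner with
#' fixed rate `logistic(beta0)`.
#'
#' @param data A data frame with binary input column `u`.
#' @param mu_meta Meta-learning rate, non-negative.
#' @param beta0 Initial log-gain; default `qlogis(0.2)`.
#' @param v0 Initial value, default 0.5.
#' @return A tibble of class `sk1_trajectory` with columns `trial`, `muhat1`
#'   (prediction `v^(k-1)`), `value`, `alpha` (per-trial gain), `beta`,
#'   `delta1`.
#' @export
filter_sk1 <- function(data, mu_meta, beta0 = stats::qlogis(0.2), v0 = 0.5) {
  require_columns(data, "u", "data")
  abort_if(!is.finite(mu_meta) || mu_meta < 0, "mu_meta must be >= 0")
  n <- nrow(data)
  abort_if(n == 0, "data must contain at least one trial")
  muhat <- numeric(n); v <- numeric(n); a <- numeric(n); b <- numeric(n)
  prev_v <- v0; prev_b <- beta0; h <- 0
  for (k in seq_len(n)) {
    muhat[k] <- prev_v
    delta <- data$u[k] - prev_v
    prev_b <- prev_b + mu_meta * delta * h
    alpha_k <- stats::plogis(prev_b)
    prev_v <- prev_v + alpha_k * delta
    h <- h * max(0, 1 - alpha_k) + alpha_k * delta
    v[k] <- prev_v; a[k] <- alpha_k; b[k] <- prev_b
  }
  traj <- tibble::tibble(trial = seq_len(n), muhat1 = muhat, value = v,
                         alpha = a, beta = b, delta1 = data$u - muhat)
  structure(traj, class = c("sk1_trajectory", class(traj)),
            params = list(mu_meta = mu_meta, beta0 = beta0, v0 = v0))
}
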