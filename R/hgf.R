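#' Logistic (sigmoid) function
#'
#' Strictly increasing logistic `1 / (1 + exp(-x))`, the link between the
#' level-2 tendency and the level-1 outcome probability of the binary
#' hierarchical Gaussian filter.
#'
#' @param x Numeric vector.
#' @return Probabilities in (0, 1); saturates smoothly at the extremes.
#' @export
logistic <- function(x) stats::plogis(x)

#' Parameters of the (social-noise) hierarchical Gaussian filter
#'
#' Collects the perceptual parameters of the three-level binary HGF and its
#' social-noise extension. `omega2` is the tonic log-volatility of the
#' level-2 tendency, `omega3` the meta-volatility (log step variance) at
#' level 3, `kappa` the level-3 to level-2 coupling (fixed to 1 by
#' convention), and `tau` the social-noise magnitude: on trials flagged as
#' perceptually uncertain the input is treated as Gaussian with variance
#' `exp(tau) / 2` around the true binary state, so larger `tau` means a less
#' trustworthy input.
#'
#' @param omega2,omega3 Real tonic (meta-)volatility parameters.
#' @param tau Real social-noise magnitude.
#' @param kappa Non-negative coupling strength; default 1.
#' @param mu2_0,sigma2_0,mu3_0,sigma3_0 Initial beliefs (mean/variance at
#'   levels 2 and 3); variances must be positive.
#' @return A list of class `hgfs_params`.
#' @export
hgfs_params <- function(omega2 = -3, omega3 = -6, tau = 0, kappa = 1,
                        mu2_0 = 0, sigma2_0 = 0.1, mu3_0 = 1, sigma3_0 = 1) {
  abort_if(sigma2_0 <= 0 || sigma3_0 <= 0, "initial variances must be > 0")
  abort_if(kappa < 0, "kappa must be >= 0")
  structure(
    list(omega2 = omega2, omega3 = omega3, tau = tau, kappa = kappa,
         mu2_0 = mu2_0, sigma2_0 = sigma2_0, mu3_0 = mu3_0,
         sigma3_0 = sigma3_0),
    class = "hgfs_params"
  )
}

#' Level-1 posterior under perceptual uncertainty
#'
#' Bayesian posterior probability that the binary state is 1 after observing
#' input `u`, when the input is perceived through Gaussian noise with
#' variance `exp(tau) / 2` around each state (the social-noise likelihood).
#' Equivalent to the density-ratio rule
#' `N(u; 1, v) * muhat1 / (N(u; 1, v) * muhat1 + N(u; 0, v) * (1 - muhat1))`
#' with `v = exp(tau)/2`, computed here in logit form for numerical
#' stability: `plogis(qlogis(muhat1) + (2u - 1) * exp(-tau))`.
#'
#' As `tau -> -Inf` the posterior recovers the noiseless rule `mu1 = u`; as
#' `tau -> +Inf` it collapses to the prior `muhat1` (no learning). For fixed
#' `u = 1` it is strictly decreasing in `tau`.
#'
#' @param u Binary input (0/1), vectorised.
#' @param muhat1 Prior probability in (0, 1), vectorised.
#' @param tau Social-noise magnitude.
#' @return Posterior probability `mu1` in (0, 1).
#' @export
#' @examples
#' level1_posterior(1, 0.5, 0)   # 1 / (1 + exp(-1))
level1_posterior <- function(u, muhat1, tau) {
  abort_if(any(muhat1 <= 0 | muhat1 >= 1),
           "muhat1 must lie strictly inside (0, 1): degenerate prior")
  abort_if(any(!u %in% c(0, 1)), "u must be binary 0/1")
  stats::plogis(stats::qlogis(muhat1) + (2 * u - 1) * exp(-tau))
}

# Keep muhat1 representable strictly inside (0, 1).
clamp_prob <- function(p, eps = 1e-15) pmin(pmax(p, eps), 1 - eps)

#' One update step of the three-level binary HGF(-S)
#'
#' Advances the belief hierarchy by one trial. The prediction
#' `muhat1 = logistic(mu2)` is formed from the previous tendency; the level-1
#' posterior is the raw input `u` on perceptually certain trials and the
#' social-noise posterior [level1_posterior()] when `noise_flag` is set; the
#' tendency and volatility levels are then updated by precision-weighted
#' prediction errors using the standard closed-form update equations of the
#' binary HGF.
#'
#' @param state List with elements `mu2`, `sigma2`, `mu3`, `sigma3` (the
#'   posterior belief after the previous trial).
#' @param u Binary input for this trial.
#' @param noise_flag Logical; `TRUE` on perceptually uncertain (emotionally
#'   incongruent) trials.
#' @param params An [hgfs_params()] object.
#' @return A list with the updated state and the trial statistics `muhat1`,
#'   `mu1`, `delta1`, `delta2`, `pihat2`, `pi3`.
#' @export
hgf_step <- function(state, u, noise_flag, params) {
  abort_if(state$sigma2 <= 0 || state$sigma3 <= 0,
           "state variances must be positive")
  kappa <- params$kappa

  muhat1 <- clamp_prob(stats::plogis(state$mu2))
  step_var2 <- exp(kappa * state$mu3 + params$omega2)
  pihat2 <- 1 / (state$sigma2 + step_var2)
  pihat3 <- 1 / (state$sigma3 + exp(params$omega3))

  mu1 <- if (isTRUE(noise_flag)) {
    level1_posterior(u, muhat1, params$tau)
  } else {
    as.numeric(u)
  }
  delta1 <- mu1 - muhat1

  pi2 <- pihat2 + muhat1 * (1 - muhat1)
  sigma2 <- 1 / pi2
  mu2 <- state$mu2 + sigma2 * delta1

  delta2 <- (sigma2 + (mu2 - state$mu2)^2) / (state$sigma2 + step_var2) - 1
  w2 <- step_var2 * pihat2
  pi3 <- pihat3 + (kappa^2 / 2) * w2 * (w2 + (2 * w2 - 1) * delta2)
  if (!is.finite(pi3) || pi3 <= 0) {
    stop("implausible-parameters: non-positive level-3 precision",
         call. = FALSE)
  }
  sigma3 <- 1 / pi3
  mu3 <- state$mu3 + sigma3 * (kappa / 2) * w2 * delta2

  list(
    mu2 = mu2, sigma2 = sigma2, mu3 = mu3, sigma3 = sigma3,
    muhat1 = muhat1, mu1 = mu1, delta1 = delta1, delta2 = delta2,
    pihat2 = pihat2, pi3 = pi3
  )
}

# Lean inner loop shared by filter_hgfs() and the fitting objective: plain
# scalar arithmetic, no per-trial closures. Returns the trajectory vectors,
# or the failing trial index when the level-3 precision goes non-positive.
hgf_filter_core <- function(u, noise, params) {
  n <- length(u)
  kappa <- params$kappa
  omega2 <- params$omega2
  e3 <- exp(params$omega3)
  et <- exp(-params$tau)
  muhat1 <- mu1 <- delta1 <- mu2 <- sigma2 <- mu3 <- sigma3 <-
    delta2 <- pihat2 <- pi3 <- numeric(n)
  m2 <- params$mu2_0; s2 <- params$sigma2_0
  m3 <- params$mu3_0; s3 <- params$sigma3_0
  for (k in seq_len(n)) {
    mh <- 1 / (1 + exp(-m2))
    if (mh < 1e-15) mh <- 1e-15 else if (mh > 1 - 1e-15) mh <- 1 - 1e-15
    sv <- exp(kappa * m3 + omega2)
    ph2 <- 1 / (s2 + sv)
    ph3 <- 1 / (s3 + e3)
    m1 <- if (noise[k]) {
      1 / (1 + exp(-(log(mh / (1 - mh)) + (2 * u[k] - 1) * et)))
    } else {
      u[k]
    }
    d1 <- m1 - mh
    s2new <- 1 / (ph2 + mh * (1 - mh))
    m2new <- m2 + s2new * d1
    d2 <- (s2new + (m2new - m2)^2) / (s2 + sv) - 1
    w2 <- sv * ph2
    p3 <- ph3 + (kappa^2 / 2) * w2 * (w2 + (2 * w2 - 1) * d2)
    if (!is.finite(p3) || p3 <= 0) return(list(fail_trial = k))
    s3 <- 1 / p3
    m3 <- m3 + s3 * (kappa / 2) * w2 * d2
    m2 <- m2new; s2 <- s2new
    muhat1[k] <- mh; mu1[k] <- m1; delta1[k] <- d1
    mu2[k] <- m2; sigma2[k] <- s2; mu3[k] <- m3; sigma3[k] <- s3
    delta2[k] <- d2; pihat2[k] <- ph2; pi3[k] <- p3
  }
  list(muhat1 = muhat1, mu1 = mu1, delta1 = delta1, mu2 = mu2,
       sigma2 = sigma2, mu3 = mu3, sigma3 = sigma3, delta2 = delta2,
       pihat2 = pihat2, pi3 = pi3)
}

#' Filter a trial sequence through the HGF or HGF-S
#'
#' Runs the three-level binary hierarchical Gaussian filter over a subject's
#' input sequence. With `social_noise = TRUE` (the HGF-S), trials flagged as
#' emotionally incongruent are processed through the noisy level-1 posterior
#' with variance `exp(tau) / 2`; with `social_noise = FALSE`, or on an
#' all-congruent dataset, the filter is the original HGF (`mu1 = u`
#' everywhere). Predictions at trial `k` depend only on trials before `k`.
#'
#' @param data A data frame with column `u` (binary input) and, when
#'   `social_noise = TRUE`, a logical column `congruent`.
#' @param params An [hgfs_params()] object.
#' @param social_noise Apply the social-noise level-1 posterior on
#'   incongruent trials? Default `TRUE`.
#' @return A tibble of class `hgfs_trajectory` with one row per trial:
#'   `trial`, `muhat1`, `mu1`, `delta1`, `mu2`, `sigma2`, `mu3`, `sigma3`,
#'   `delta2`, `pihat2`, `pi3`, `noise_flag`. An "implausible-parameters"
#'   error identifies the failing trial.
#' @export
filter_hgfs <- function(data, params, social_noise = TRUE) {
  require_columns(data, "u", "data")
  n <- nrow(data)
  abort_if(n == 0, "data must contain at least one trial")
  if (social_noise) {
    require_columns(data, "congruent", "data")
    noise_flags <- !data$congruent
  } else {
    noise_flags <- rep(FALSE, n)
  }

  core <- hgf_filter_core(data$u, noise_flags, params)
  if (!is.null(core$fail_trial)) {
    stop(sprintf(
      "implausible-parameters: non-positive level-3 precision (trial %d)",
      core$fail_trial), call. = FALSE)
  }
  traj <- tibble::tibble(
    trial = seq_len(n),
    muhat1 = core$muhat1, mu1 = core$mu1, delta1 = core$delta1,
    mu2 = core$mu2, sigma2 = core$sigma2, mu3 = core$mu3,
    sigma3 = core$sigma3, delta2 = core$delta2, pihat2 = core$pihat2,
    pi3 = core$pi3, noise_flag = noise_flags
  )
  structure(traj, class = c("hgfs_trajectory", class(traj)),
            params = params, social_noise = social_noise)
}

#' Belief fluctuation of a trajectory
#'
#' Total variation of the belief at one level of the hierarchy: the sum of
#' absolute between-trial differences `sum(|mu^(k+1) - mu^(k)|)`. Used to
#' quantify how much a learner's belief moves over a task run; perceptual
#' (social) noise damps it at every level.
#'
#' @param trajectory A trajectory tibble with columns `mu1`, `mu2`, `mu3`
#'   (e.g. from [filter_hgfs()]).
#' @param level Hierarchy level, 1, 2 or 3.
#' @return A non-negative number.
#' @export
belief_fluctuation <- function(trajectory, level = 1) {
  abort_if(!level %in% 1:3, "level must be 1, 2 or 3")
  col <- paste0("mu", level)
  require_columns(trajectory, col, "trajectory")
  x <- trajectory[[col]]
  abort_if(length(x) < 2, "trajectory must contain at least 2 trials")
  sum(abs(diff(x)))
}
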