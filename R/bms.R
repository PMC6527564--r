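#' Exceedance probabilities from Dirichlet parameters
#'
#' Monte-Carlo estimate of `P(model m has the largest population frequency)`
#' under a `Dirichlet(alpha)` posterior, by sampling frequencies and
#' tallying the argmax (ties, a measure-zero event, go to the lowest
#' index). For two models the Beta-CDF closed form
#' `P(r1 > 1/2) = 1 - pbeta(0.5, alpha1, alpha2)` is an exact cross-check.
#'
#' @param alpha Positive Dirichlet parameters, one per model.
#' @param mc_samples Number of Monte-Carlo samples (default 1e6).
#' @param seed Integer seed for the sampler.
#' @return A probability vector summing to 1.
#' @export
exceedance_from_alpha <- function(alpha, mc_samples = 1e6, seed = 1L) {
  abort_if(any(!is.finite(alpha) | alpha <= 0), "alpha must be positive")
  m <- length(alpha)
  if (m == 1) return(1)
  with_seed(derive_seed(seed, 55L), {
    g <- matrix(stats::rgamma(mc_samples * m, shape = rep(alpha, each = mc_samples)),
                nrow = mc_samples, ncol = m)
    tabulate(max.col(g, ties.method = "first"), m) / mc_samples
  })
}

# Variational free energy of the random-effects model at the converged
# (alpha, u) -- the standard Dirichlet-multinomial bound.
rfx_free_energy <- function(lme, u, alpha, alpha0) {
  asum <- sum(alpha)
  dg <- digamma(alpha) - digamma(asum)
  elogp <- sum(u * sweep(lme, 2, dg, "+"))
  ent_u <- -sum(u[u > 0] * log(u[u > 0]))
  ldirich <- lgamma(sum(alpha0)) - sum(lgamma(alpha0)) -
    lgamma(asum) + sum(lgamma(alpha)) +
    sum((alpha0 - alpha) * dg)
  elogp + ent_u + ldirich
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects: model
#' frequencies follow a Dirichlet whose parameters are iterated by the
#' standard variational scheme from the per-subject log model evidences.
#' Reports expected model frequencies, exceedance probabilities (EP, by
#' Dirichlet Monte-Carlo), the Bayes omnibus risk (BOR; posterior
#' probability that all models are equally frequent, from the free-energy
#' comparison of the null and the fitted alternative), and protected
#' exceedance probabilities `PXP = EP * (1 - BOR) + BOR / M`.
#'
#' @param log_evidence Subjects x models matrix or data frame of log model
#'   evidences. `-Inf` is allowed (a model ruled out for a subject); `+Inf`
#'   and `NaN` are rejected. Column names identify the models.
#' @param prior_alpha Dirichlet prior count per model (default 1,
#'   uninformative).
#' @param mc_samples Monte-Carlo samples for the EP estimate.
#' @param seed Integer seed for the EP sampler.
#' @param tol Convergence tolerance on the alpha updates (default 1e-8).
#' @return An object of class `bms_result` with fields `dirichlet_alpha`,
#'   `expected_frequencies`, `exceedance_prob`, `protected_exceedance_prob`,
#'   `bayes_omnibus_risk`, `model_attribution` (subjects x models posterior),
#'   `n_mc_samples`, `seed`. Use [tidy()] for a per-model tibble.
#' @export
rfx_bms <- function(log_evidence, prior_alpha = 1, mc_samples = 1e6,
                    seed = 1L, tol = 1e-8) {
  lme <- as.matrix(log_evidence)
  abort_if(any(is.nan(lme)) || any(lme == Inf),
           "log_evidence must not contain NaN or +Inf")
  n <- nrow(lme); m <- ncol(lme)
  abort_if(n < 1 || m < 1, "need at least one subject and one model")
  models <- colnames(lme)
  if (is.null(models)) models <- paste0("model", seq_len(m))
  # Shift per subject: posterior attribution only depends on differences.
  lme <- sweep(lme, 1, apply(lme, 1, max))

  alpha0 <- rep(prior_alpha, m)
  alpha <- alpha0
  u <- matrix(1 / m, n, m)
  for (iter in seq_len(10000)) {
    lu <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  ef <- alpha / sum(alpha)
  ep <- if (m == 1) 1 else
    exceedance_from_alpha(alpha, mc_samples = mc_samples, seed = seed)

  # BOR: null model (all frequencies fixed equal) vs fitted alternative.
  f0 <- sum(apply(lme, 1, logsumexp) - log(m))
  f1 <- rfx_free_energy(lme, u, alpha, alpha0)
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- ep * (1 - bor) + bor / m

  structure(list(
    models = models,
    dirichlet_alpha = stats::setNames(alpha, models),
    expected_frequencies = stats::setNames(ef, models),
    exceedance_prob = stats::setNames(ep, models),
    protected_exceedance_prob = stats::setNames(pxp, models),
    bayes_omnibus_risk = bor,
    model_attribution = u,
    n_subjects = n, n_mc_samples = mc_samples, seed = seed
  ), class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf("<bms_result: %d subjects, %d models; BOR = %.3f>\n",
              x$n_subjects, length(x$models), x$bayes_omnibus_risk))
  df <- data.frame(
    model = x$models,
    alpha = round(unname(x$dirichlet_alpha), 3),
    freq = round(unname(x$expected_frequencies), 3),
    ep = round(unname(x$exceedance_prob), 4),
    pxp = round(unname(x$protected_exceedance_prob), 4)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Fit every model to every subject of a cohort
#'
#' Convenience wrapper running [fit_map()] for each subject x model pair and
#' collecting the log evidences in the subjects x models matrix consumed by
#' [rfx_bms()].
#'
#' @param cohort A nested cohort tibble from [simulate_cohort()] (or any
#'   tibble with `subject` and a `data` list-column of per-trial tables).
#' @param models Character vector of models to fit.
#' @param n_restarts,seed Passed to [fit_map()].
#' @return A list with `log_evidence` (matrix) and `fits` (nested tibble of
#'   `hgfs_fit` objects).
#' @export
fit_cohort <- function(cohort, models = c("sk1", "rw", "hgf", "hgfs"),
                       n_restarts = 8, seed = 1L) {
  require_columns(cohort, c("subject", "data"), "cohort")
  fits <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    purrr::map_dfr(models, function(mod) {
      fit <- fit_map(cohort$data[[i]], model = mod, n_restarts = n_restarts,
                     seed = derive_seed(seed, i, match(mod, models)))
      tibble::tibble(subject = cohort$subject[i], model = mod,
                     log_evidence = fit$log_evidence, fit = list(fit))
    })
  })
  lme <- matrix(fits$log_evidence, nrow = nrow(cohort), ncol = length(models),
                byrow = TRUE, dimnames = list(NULL, models))
  list(log_evidence = lme, fits = fits)
}
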