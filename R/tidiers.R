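#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a model fit
#'
#' One row per free parameter with the MAP estimate in native and
#' unconstrained space.
#'
#' @param x An `hgfs_fit` from [fit_map()].
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `estimate`, `unconstrained`.
#' @method tidy hgfs_fit
#' @export
tidy.hgfs_fit <- function(x, ...) {
  if (x$failed) {
    return(tibble::tibble(parameter = character(), estimate = double(),
                          unconstrained = double()))
  }
  tibble::tibble(
    parameter = names(x$estimates),
    estimate = vapply(x$estimates, identity, double(1)),
    unconstrained = unname(x$theta)
  )
}

#' Glance at a model fit
#'
#' @param x An `hgfs_fit` from [fit_map()].
#' @param ... Unused.
#' @return A one-row tibble of fit diagnostics.
#' @method glance hgfs_fit
#' @export
glance.hgfs_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, n_trials = x$n_trials, log_joint = x$log_joint,
    log_lik = x$log_lik, log_evidence = x$log_evidence,
    evidence_method = x$evidence_method, converged = x$converged,
    failed = x$failed, n_restarts_used = x$n_restarts_used
  )
}

#' Tidy a Bayesian model selection result
#'
#' @param x A `bms_result` from [rfx_bms()].
#' @param ... Unused.
#' @return A tibble with one row per model: `model`, `alpha`,
#'   `expected_frequency`, `exceedance_prob`, `protected_exceedance_prob`.
#' @method tidy bms_result
#' @export
tidy.bms_result <- function(x, ...) {
  tibble::tibble(
    model = x$models,
    alpha = unname(x$dirichlet_alpha),
    expected_frequency = unname(x$expected_frequencies),
    exceedance_prob = unname(x$exceedance_prob),
    protected_exceedance_prob = unname(x$protected_exceedance_prob)
  )
}

#' Glance at a Bayesian model selection result
#'
#' @param x A `bms_result` from [rfx_bms()].
#' @param ... Unused.
#' @return A one-row tibble: `n_subjects`, `bayes_omnibus_risk`,
#'   `n_mc_samples`, `best_model` (highest exceedance probability).
#' @method glance bms_result
#' @export
glance.bms_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    bayes_omnibus_risk = x$bayes_omnibus_risk,
    n_mc_samples = x$n_mc_samples,
    best_model = x$models[which.max(x$exceedance_prob)]
  )
}

#' Tidy a perturbation experiment
#'
#' @param x A `perturbation_result` from [tau_perturbation_experiment()].
#' @param ... Unused.
#' @return The per-outcome paired-test tibble (`outcome`, arm means, `t`,
#'   `df`, `p`, `n`).
#' @method tidy perturbation_result
#' @export
tidy.perturbation_result <- function(x, ...) x$tests

#' Glance at a perturbation experiment
#'
#' @param x A `perturbation_result` from [tau_perturbation_experiment()].
#' @param ... Unused.
#' @return A one-row tibble of the experiment settings.
#' @method glance perturbation_result
#' @export
glance.perturbation_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subjects), delta_tau = x$delta_tau,
    n_reps = x$n_reps, seed = x$seed
  )
}
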