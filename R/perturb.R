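#' Social-noise perturbation experiment
#'
#' Tests, by simulation, what a uniform increase of the social-noise
#' parameter does to learning and to subsequent decisions. For every subject
#' and repetition, an environment is drawn and the subject's HGF-S agent is
#' simulated twice on it -- once with the subject's own `tau` and once with
#' `tau + delta_tau` -- using common random numbers, so a zero perturbation
#' reproduces the original arm bit for bit. Per subject the belief
#' fluctuation (total variation of `mu1`, `mu2`, `mu3`) and the
#' low-irreducible-uncertainty SN_d are averaged over repetitions in each
#' arm, and the arms are compared by paired t-tests across subjects.
#' Raising social noise damps belief fluctuation at every level of the
#' hierarchy and inflates SN_d.
#'
#' @param fits A data frame with one row per subject and columns `omega2`,
#'   `omega3`, `tau`, `zeta` (native space), e.g. the parameter columns of a
#'   [simulate_cohort()] result or tidied MAP estimates.
#' @param schedule Trial schedule from [generate_schedule()].
#' @param delta_tau Amount added to each subject's `tau` (default 3).
#' @param n_reps Simulation repetitions per subject (default 100).
#' @param seed Master seed.
#' @return An object of class `perturbation_result`: `subjects` (per-subject
#'   tibble of mean outcomes in both arms), `tests` (paired t-test per
#'   outcome), and the settings. [tidy()] returns the per-subject tibble,
#'   [glance()] the tests.
#' @export
tau_perturbation_experiment <- function(fits, schedule, delta_tau = 3,
                                        n_reps = 100, seed = 1L) {
  require_columns(fits, c("omega2", "omega3", "tau", "zeta"), "fits")
  abort_if(n_reps < 1, "n_reps must be >= 1")
  n_sub <- nrow(fits)
  abort_if(n_sub < 1, "fits must contain at least one subject")

  run_arm <- function(pars, env, choice_seed) {
    dat <- simulate_subject(env, model = "hgfs", params = pars,
                            seed = choice_seed)
    list(
      fluct1 = sum(abs(diff(dat$mu1))),
      fluct2 = sum(abs(diff(dat$mu2))),
      fluct3 = sum(abs(diff(dat$mu3))),
      snd_low = decision_change_table(dat)$snd[1]
    )
  }

  subjects <- purrr::map_dfr(seq_len(n_sub), function(i) {
    base <- list(omega2 = fits$omega2[i], omega3 = fits$omega3[i],
                 tau = fits$tau[i], zeta = fits$zeta[i])
    pert <- base
    pert$tau <- base$tau + delta_tau
    reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
      env <- simulate_environment(schedule, seed = derive_seed(seed, i, r, 1L))
      cs <- derive_seed(seed, i, r, 2L)
      o <- tryCatch(run_arm(base, env, cs), error = function(e) NULL)
      p <- tryCatch(run_arm(pert, env, cs), error = function(e) NULL)
      # Filter failures are excluded symmetrically from both arms.
      if (is.null(o) || is.null(p)) return(NULL)
      tibble::tibble(
        fluct1_orig = o$fluct1, fluct2_orig = o$fluct2, fluct3_orig = o$fluct3,
        snd_low_orig = o$snd_low,
        fluct1_pert = p$fluct1, fluct2_pert = p$fluct2, fluct3_pert = p$fluct3,
        snd_low_pert = p$snd_low
      )
    })
    out <- dplyr::summarise(reps, dplyr::across(dplyr::everything(),
                                                ~ mean(.x, na.rm = TRUE)))
    out$subject <- i
    out$n_reps_used <- nrow(reps)
    out$n_snd_defined <- sum(is.finite(reps$snd_low_orig) &
                               is.finite(reps$snd_low_pert))
    out
  })

  paired <- function(orig, pert) {
    keep <- is.finite(orig) & is.finite(pert)
    d <- pert[keep] - orig[keep]
    if (length(d) < 2 || stats::sd(d) == 0) {
      return(tibble::tibble(mean_orig = mean(orig[keep]),
                            mean_pert = mean(pert[keep]),
                            t = 0, df = length(d) - 1,
                            p = if (all(d == 0)) 1 else NA_real_,
                            n = length(d)))
    }
    tt <- stats::t.test(pert[keep], orig[keep], paired = TRUE)
    tibble::tibble(mean_orig = mean(orig[keep]), mean_pert = mean(pert[keep]),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, n = length(d))
  }
  tests <- dplyr::bind_rows(
    dplyr::mutate(paired(subjects$fluct1_orig, subjects$fluct1_pert),
                  outcome = "fluctuation_level1", .before = 1),
    dplyr::mutate(paired(subjects$fluct2_orig, subjects$fluct2_pert),
                  outcome = "fluctuation_level2", .before = 1),
    dplyr::mutate(paired(subjects$fluct3_orig, subjects$fluct3_pert),
                  outcome = "fluctuation_level3", .before = 1),
    dplyr::mutate(paired(subjects$snd_low_orig, subjects$snd_low_pert),
                  outcome = "snd_low", .before = 1)
  )

  structure(list(subjects = subjects, tests = tests, delta_tau = delta_tau,
                 n_reps = n_reps, seed = seed),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf(
    "<perturbation_result: %d subjects, delta_tau = %g, %d reps>\n",
    nrow(x$subjects), x$delta_tau, x$n_reps))
  print(as.data.frame(x$tests), row.names = FALSE, digits = 4)
  invisible(x)
}
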