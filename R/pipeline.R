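#' End-to-end analysis pipeline
#'
#' Runs the full study pipeline -- simulate a cohort, fit all four learning
#' models, compare them by random-effects Bayesian model selection, compute
#' the SN_d behavioural statistics and the tau--SN_d correlation, run the
#' social-noise perturbation experiment, and a parameter-recovery check --
#' writing every stage's artifact (CSV/JSON) plus a run manifest into
#' `out_dir`. Every stochastic stage receives a sub-seed derived from the
#' master seed, so re-running with an identical configuration reproduces
#' identical artifacts.
#'
#' @param out_dir Output directory (created if missing).
#' @param blocks Block structure for the schedule (default [pal_blocks()]).
#' @param spec A [cohort_spec()] describing the simulated cohort.
#' @param seed Master seed.
#' @param stages Which stages to run, a subset of
#'   `c("simulate", "fit", "compare", "analyse", "perturb", "recover")`;
#'   later stages require the in-memory results of earlier ones, so the
#'   subset must be a prefix-closed chain.
#' @param n_restarts Optimizer restarts per fit.
#' @param mc_samples Monte-Carlo samples for exceedance probabilities.
#' @param delta_tau,n_perturb_reps Perturbation-experiment settings.
#' @param n_recovery_subjects Cohort size for the recovery stage.
#' @return Invisibly, a list with the in-memory results of every stage run.
#' @export
run_pipeline <- function(out_dir,
                         blocks = pal_blocks(),
                         spec = cohort_spec(),
                         seed = 1L,
                         stages = c("simulate", "fit", "compare", "analyse",
                                    "perturb", "recover"),
                         n_restarts = 8,
                         mc_samples = 1e6,
                         delta_tau = 3,
                         n_perturb_reps = 100,
                         n_recovery_subjects = 30) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  schedule <- generate_schedule(blocks, seed = derive_seed(seed, 1L))
  write_trials_csv(schedule, file.path(out_dir, "schedule.csv"))
  results$schedule <- schedule

  if ("simulate" %in% stages) {
    cohort <- simulate_cohort(schedule, spec, seed = derive_seed(seed, 2L))
    results$cohort <- cohort
    flat <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      dplyr::mutate(cohort$data[[i]], subject = cohort$subject[i],
                    .before = 1)
    })
    write_trials_csv(flat, file.path(out_dir, "cohort_trials.csv"))
    write_trials_csv(dplyr::select(cohort, -"data"),
                     file.path(out_dir, "cohort_params.csv"))
  }

  if ("fit" %in% stages) {
    abort_if(is.null(results$cohort), "'fit' requires the simulate stage")
    fitres <- fit_cohort(results$cohort, n_restarts = n_restarts,
                         seed = derive_seed(seed, 3L))
    results$fits <- fitres
    write_fits_json(fitres$fits, file.path(out_dir, "fits.json"))
    lme_df <- tibble::as_tibble(fitres$log_evidence)
    lme_df$subject <- results$cohort$subject
    readr::write_csv(lme_df[, c("subject", colnames(fitres$log_evidence))],
                     file.path(out_dir, "evidences.csv"))
  }

  if ("compare" %in% stages) {
    abort_if(is.null(results$fits), "'compare' requires the fit stage")
    bms <- rfx_bms(results$fits$log_evidence, mc_samples = mc_samples,
                   seed = derive_seed(seed, 4L))
    results$bms <- bms
    jsonlite::write_json(
      list(models = bms$models,
           dirichlet_alpha = unname(bms$dirichlet_alpha),
           expected_frequencies = unname(bms$expected_frequencies),
           exceedance_prob = unname(bms$exceedance_prob),
           protected_exceedance_prob = unname(bms$protected_exceedance_prob),
           bayes_omnibus_risk = bms$bayes_omnibus_risk,
           n_mc_samples = bms$n_mc_samples, seed = bms$seed),
      file.path(out_dir, "bms.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  if ("analyse" %in% stages) {
    abort_if(is.null(results$cohort), "'analyse' requires the simulate stage")
    snd_tbl <- purrr::map_dfr(seq_len(nrow(results$cohort)), function(i) {
      dplyr::mutate(decision_change_table(results$cohort$data[[i]]),
                    subject = results$cohort$subject[i], .before = 1)
    })
    results$snd <- snd_tbl
    readr::write_csv(snd_tbl, file.path(out_dir, "snd.csv"))
    low <- snd_tbl[snd_tbl$condition == "low", ]
    high <- snd_tbl[snd_tbl$condition == "high", ]
    tests <- list(
      low = as.list(snd_group_test(low$snd)),
      high = as.list(snd_group_test(high$snd))
    )
    if (!is.null(results$fits)) {
      hgfs_fits <- results$fits$fits[results$fits$fits$model == "hgfs", ]
      tau_hat <- vapply(hgfs_fits$fit, function(f) {
        if (f$failed) NA_real_ else f$estimates$tau
      }, double(1))
      tests$tau_snd_low <- as.list(tau_snd_correlation(tau_hat, low$snd))
      results$tau_hat <- tau_hat
    }
    results$snd_tests <- tests
    jsonlite::write_json(tests, file.path(out_dir, "snd_tests.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if ("perturb" %in% stages) {
    abort_if(is.null(results$cohort), "'perturb' requires the simulate stage")
    abort_if(spec$model != "hgfs",
             "perturbation requires an HGF-S generating model")
    pert <- tau_perturbation_experiment(
      dplyr::select(results$cohort, -"data"), schedule,
      delta_tau = delta_tau, n_reps = n_perturb_reps,
      seed = derive_seed(seed, 5L))
    results$perturbation <- pert
    readr::write_csv(pert$subjects, file.path(out_dir, "perturbation.csv"))
    readr::write_csv(pert$tests, file.path(out_dir, "perturbation_tests.csv"))
  }

  if ("recover" %in% stages) {
    rec_spec <- spec
    rec_spec$n_subjects <- as.integer(n_recovery_subjects)
    rec <- parameter_recovery(schedule, rec_spec, n_reps = 1,
                              seed = derive_seed(seed, 6L),
                              n_restarts = n_restarts)
    results$recovery <- rec
    readr::write_csv(rec, file.path(out_dir, "recovery.csv"))
    readr::write_csv(recovery_summary(rec),
                     file.path(out_dir, "recovery_summary.csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("socialnoise")),
    seed = seed,
    stages = stages,
    config_hash = rlang::hash(list(blocks = blocks, spec = unclass(spec),
                                   seed = seed, n_restarts = n_restarts,
                                   mc_samples = mc_samples,
                                   delta_tau = delta_tau,
                                   n_perturb_reps = n_perturb_reps,
                                   n_recovery_subjects = n_recovery_subjects)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
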