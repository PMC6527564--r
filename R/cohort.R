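#' Specify a synthetic cohort of model-driven agents
#'
#' Describes a population of simulated subjects: how many, which generating
#' model drives their choices, and the population distributions their
#' individual parameters are drawn from. Perceptual parameters (`omega2`,
#' `omega3`, `tau`) are Gaussian on their native scale; `zeta` is
#' log-normal (Gaussian on `log zeta`), `alpha` logit-normal, `mu_meta`
#' log-normal, matching the unconstrained spaces used for estimation.
#'
#' The defaults describe the reference study conditions used throughout the
#' package's simulation experiments: 34 agents driven by the HGF-S with mild
#' baseline social noise (`tau ~ N(-1, 0.3^2)`, so emotionally incongruent
#' feedback is degraded but still informative), active volatility tracking
#' (`omega3 ~ N(-3, 0.3^2)`), and fairly deterministic responding
#' (`log zeta ~ N(log 20, 0.3^2)`). In this regime the social-noise
#' mechanism is identifiable against the plain HGF and raising `tau` damps
#' belief fluctuation at every level of the hierarchy.
#'
#' @param n_subjects Number of agents (>= 0).
#' @param model Generating model: `"hgfs"`, `"hgf"`, `"rw"` or `"sk1"`.
#' @param omega2,omega3,tau,log_zeta,logit_alpha,log_mu_meta Length-2 numeric
#'   vectors `c(mean, sd)` of the population distribution in the parameter's
#'   unconstrained space; sds must be >= 0.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 34, model = c("hgfs", "hgf", "rw", "sk1"),
                        omega2 = c(-3, 0.5), omega3 = c(-3, 0.3),
                        tau = c(-1, 0.3),
                        log_zeta = c(log(20), 0.3), logit_alpha = c(0, 1),
                        log_mu_meta = c(-2, 1)) {
  model <- match.arg(model)
  abort_if(n_subjects < 0, "n_subjects must be >= 0")
  dists <- list(omega2 = omega2, omega3 = omega3, tau = tau,
                log_zeta = log_zeta, logit_alpha = logit_alpha,
                log_mu_meta = log_mu_meta)
  for (nm in names(dists)) {
    d <- dists[[nm]]
    abort_if(length(d) != 2 || any(!is.finite(d)) || d[2] < 0,
             sprintf("%s must be c(mean, sd) with sd >= 0", nm))
  }
  structure(c(list(n_subjects = as.integer(n_subjects), model = model), dists),
            class = "cohort_spec")
}

# Draw one agent's native-space parameters from the population spec.
draw_subject_params <- function(spec) {
  g <- function(d) stats::rnorm(1, d[1], d[2])
  switch(spec$model,
    hgfs = list(omega2 = g(spec$omega2), omega3 = g(spec$omega3),
                tau = g(spec$tau), zeta = exp(g(spec$log_zeta))),
    hgf = list(omega2 = g(spec$omega2), omega3 = g(spec$omega3),
               zeta = exp(g(spec$log_zeta))),
    rw = list(alpha = stats::plogis(g(spec$logit_alpha)),
              zeta = exp(g(spec$log_zeta))),
    sk1 = list(mu_meta = exp(g(spec$log_mu_meta)),
               zeta = exp(g(spec$log_zeta)))
  )
}

#' Simulate one agent performing the task
#'
#' Runs a learning model forward through an already-simulated environment,
#' trial by trial: form the prediction `muhat1`, choose through the
#' unit-square sigmoid, observe the contingency-coded outcome `u`, derive
#' correctness and emotional congruency from the pre-assigned face valence,
#' and update beliefs (with the social-noise level-1 posterior on
#' incongruent trials when the agent is an HGF-S).
#'
#' @param env A schedule with outcomes, from [simulate_environment()].
#' @param model `"hgfs"`, `"hgf"`, `"rw"` or `"sk1"`.
#' @param params Named list of native-space parameters: `omega2`, `omega3`,
#'   `tau` (hgfs), `zeta` for the HGF family; `alpha`, `zeta` for RW;
#'   `mu_meta`, `zeta` for SK1.
#' @param seed Integer seed for the choice stream.
#' @return A tibble (one row per trial) extending `env` with `choice_prob`,
#'   `y`, `choice_gender`, `correct`, `congruent`, and the generating
#'   model's belief trajectory columns; attribute `params` records the
#'   generating parameters.
#' @export
simulate_subject <- function(env, model = c("hgfs", "hgf", "rw", "sk1"),
                             params, seed = 1L) {
  model <- match.arg(model)
  require_columns(env, c("u", "cue", "face_valence"), "env")
  n <- nrow(env)
  abort_if(n == 0, "env must contain at least one trial")
  zeta <- params$zeta
  abort_if(is.null(zeta) || zeta <= 0, "params$zeta must be > 0")

  hgf_family <- model %in% c("hgfs", "hgf")
  if (hgf_family) {
    p <- hgfs_params(omega2 = params$omega2, omega3 = params$omega3,
                     tau = if (model == "hgfs") params$tau else 0)
    state <- list(mu2 = p$mu2_0, sigma2 = p$sigma2_0,
                  mu3 = p$mu3_0, sigma3 = p$sigma3_0)
  } else if (model == "rw") {
    abort_if(params$alpha <= 0 || params$alpha >= 1,
             "params$alpha must lie in (0, 1)")
    v <- 0.5
  } else {
    abort_if(params$mu_meta < 0, "params$mu_meta must be >= 0")
    v <- 0.5; beta <- stats::qlogis(0.2); h <- 0
  }

  muhat <- numeric(n); cp <- numeric(n); y <- integer(n)
  correct <- logical(n); congruent <- logical(n)
  traj_rows <- if (hgf_family) vector("list", n) else NULL

  with_seed(seed, {
    for (k in seq_len(n)) {
      muhat[k] <- clamp_prob(if (hgf_family) stats::plogis(state$mu2) else v)
      cp[k] <- choice_probability(muhat[k], zeta)
      y[k] <- simulate_choice(cp[k])
      correct[k] <- y[k] == env$u[k]
      congruent[k] <- (correct[k] & env$face_valence[k] == "happy") |
        (!correct[k] & env$face_valence[k] == "sad")
      if (hgf_family) {
        noise <- model == "hgfs" && !congruent[k]
        state <- hgf_step(state, env$u[k], noise, p)
        traj_rows[[k]] <- state
      } else if (model == "rw") {
        v <- v + params$alpha * (env$u[k] - v)
      } else {
        delta <- env$u[k] - v
        beta <- beta + params$mu_meta * delta * h
        a_k <- stats::plogis(beta)
        v <- v + a_k * delta
        h <- h * max(0, 1 - a_k) + a_k * delta
      }
    }
  })

  out <- env
  out$muhat1 <- muhat
  out$choice_prob <- cp
  out$y <- y
  out$choice_gender <- ifelse((out$cue == "high") == (y == 1L),
                              "female", "male")
  out$correct <- correct
  out$congruent <- congruent
  if (hgf_family) {
    for (col in c("mu1", "mu2", "sigma2", "mu3", "sigma3")) {
      out[[col]] <- vapply(traj_rows, `[[`, double(1), col)
    }
  }
  structure(out, params = params, model = model)
}

#' Simulate a synthetic cohort
#'
#' Draws per-subject parameters from the population distributions of a
#' [cohort_spec()] and simulates each agent on the given schedule with its
#' own derived environment and choice sub-seeds. A subject whose filter
#' fails (non-positive precision from an extreme parameter draw) is
#' regenerated with a fresh sub-seed; the number of regenerations is
#' attached as attribute `n_regenerated`.
#'
#' @param schedule A trial schedule from [generate_schedule()].
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed; the cohort is a pure function of
#'   `(schedule, spec, seed)`.
#' @param shared_environment If `TRUE` all subjects experience the same
#'   outcome sequence; default `FALSE` (each subject gets an independent
#'   draw of the environment, as for independent participants).
#' @return A nested tibble with one row per subject: `subject`, the drawn
#'   native-space parameters as columns, and `data` (list-column of
#'   per-trial tibbles from [simulate_subject()]).
#' @export
simulate_cohort <- function(schedule, spec = cohort_spec(), seed = 1L,
                            shared_environment = FALSE) {
  abort_if(!inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  n_sub <- spec$n_subjects
  if (n_sub == 0) {
    return(tibble::tibble(subject = integer(), data = list()))
  }
  rows <- vector("list", n_sub)
  n_regen <- 0L
  for (i in seq_len(n_sub)) {
    attempt <- 0L
    repeat {
      sub_seed <- derive_seed(seed, i, attempt)
      pars <- with_seed(derive_seed(sub_seed, 1L), draw_subject_params(spec))
      env_seed <- if (shared_environment) derive_seed(seed, 0L, 2L) else
        derive_seed(sub_seed, 2L)
      env <- simulate_environment(schedule, seed = env_seed)
      dat <- tryCatch(
        simulate_subject(env, model = spec$model, params = pars,
                         seed = derive_seed(sub_seed, 3L)),
        error = function(e) NULL
      )
      if (!is.null(dat)) break
      attempt <- attempt + 1L
      n_regen <- n_regen + 1L
      abort_if(attempt > 50L, "subject regeneration failed 50 times")
    }
    rows[[i]] <- tibble::tibble(subject = i, !!!pars, data = list(dat))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_regenerated") <- n_regen
  attr(out, "spec") <- spec
  out
}
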