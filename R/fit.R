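# Free parameters per model, named in their unconstrained (estimation)
# space: identity for omega2/omega3/tau, log for zeta and mu_meta, logit for
# alpha. kappa is fixed (default 1) and never optimized.
model_free_params <- function(model) {
  switch(model,
    hgfs = c("omega2", "omega3", "tau", "log_zeta"),
    hgf = c("omega2", "omega3", "log_zeta"),
    rw = c("logit_alpha", "log_zeta"),
    sk1 = c("log_mu_meta", "log_zeta"),
    stop("unknown model: ", model, call. = FALSE)
  )
}

# Unconstrained vector -> native-space parameter list.
to_native <- function(theta, model) {
  switch(model,
    hgfs = list(omega2 = theta[["omega2"]], omega3 = theta[["omega3"]],
                tau = theta[["tau"]], zeta = exp(theta[["log_zeta"]])),
    hgf = list(omega2 = theta[["omega2"]], omega3 = theta[["omega3"]],
               zeta = exp(theta[["log_zeta"]])),
    rw = list(alpha = stats::plogis(theta[["logit_alpha"]]),
              zeta = exp(theta[["log_zeta"]])),
    sk1 = list(mu_meta = exp(theta[["log_mu_meta"]]),
               zeta = exp(theta[["log_zeta"]]))
  )
}

#' Default priors for model fitting
#'
#' Independent Gaussian priors in each free parameter's unconstrained space:
#' `omega2 ~ N(-3, 16)`, `omega3 ~ N(-6, 16)`, `tau ~ N(0, 4)`,
#' `log zeta ~ N(log 48, 1)`, `logit alpha ~ N(0, 1)`,
#' `log mu_meta ~ N(-2, 1)` (variances). These follow the conventional
#' weakly-informative settings for binary HGF-family fitting and are fully
#' configurable.
#'
#' @param model `"hgfs"`, `"hgf"`, `"rw"` or `"sk1"`.
#' @return Named list, one `c(mean, sd)` pair per free parameter.
#' @export
default_priors <- function(model = c("hgfs", "hgf", "rw", "sk1")) {
  model <- match.arg(model)
  all <- list(
    omega2 = c(-3, 4), omega3 = c(-6, 4), tau = c(0, 2),
    log_zeta = c(log(48), 1), logit_alpha = c(0, 1), log_mu_meta = c(-2, 1)
  )
  all[model_free_params(model)]
}

# Log joint (log-likelihood of choices + log prior) at an unconstrained
# parameter vector; -Inf when the filter rejects the parameter point.
log_joint_at <- function(theta, data, model, priors, kappa = 1) {
  native <- to_native(theta, model)
  lp <- sum(vapply(names(theta), function(nm) {
    stats::dnorm(theta[[nm]], priors[[nm]][1], priors[[nm]][2], log = TRUE)
  }, double(1)))
  if (nrow(data) == 0) return(lp)
  muhat <- if (model %in% c("hgfs", "hgf")) {
    pars <- hgfs_params(native$omega2, native$omega3,
                        tau = if (model == "hgfs") native$tau else 0,
                        kappa = kappa)
    noise <- if (model == "hgfs") !data$congruent else rep(FALSE, nrow(data))
    core <- hgf_filter_core(data$u, noise, pars)
    if (!is.null(core$fail_trial)) return(-Inf)
    core$muhat1
  } else if (model == "rw") {
    if (native$alpha <= 0 || native$alpha >= 1) return(-Inf)
    u <- data$u
    n <- length(u)
    mh <- numeric(n)
    v <- 0.5
    for (k in seq_len(n)) {
      mh[k] <- v
      v <- v + native$alpha * (u[k] - v)
    }
    mh
  } else {
    u <- data$u
    n <- length(u)
    mh <- numeric(n)
    v <- 0.5; b <- stats::qlogis(0.2); h <- 0
    for (k in seq_len(n)) {
      mh[k] <- v
      d <- u[k] - v
      b <- b + native$mu_meta * d * h
      a <- 1 / (1 + exp(-b))
      v <- v + a * d
      h <- h * max(0, 1 - a) + a * d
    }
    mh
  }
  p <- stats::plogis(native$zeta * stats::qlogis(clamp_prob(muhat)))
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(data$y * log(p) + (1 - data$y) * log(1 - p)) + lp
}

# Central-difference gradient of the log joint, for the convergence check.
numeric_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, double(1))
}

#' MAP fit of one learning model to one subject
#'
#' Maximizes the log joint (choice log-likelihood plus Gaussian prior) over
#' the model's free parameters in unconstrained space, by quasi-Newton
#' (BFGS) from multiple restarts: the prior mean plus `n_restarts - 1` prior
#' draws. Parameter points at which the filter fails (non-positive
#' precision) score `-Inf`. The log model evidence is a Laplace
#' approximation at the optimum, falling back to BIC when the negative
#' Hessian is not positive definite. The fit is flagged converged when the
#' gradient norm at the optimum is below `1e-5` and the best two restarts
#' agree within `1e-3` log-joint units.
#'
#' @param data A per-trial tibble with columns `u`, `y` and (for the HGF-S)
#'   `congruent`; typically from [simulate_subject()] or [encode_trials()].
#'   Zero-information (empty) data returns the prior means with log
#'   evidence 0.
#' @param model `"hgfs"`, `"hgf"`, `"rw"` or `"sk1"`.
#' @param priors Named list of `c(mean, sd)` prior pairs in unconstrained
#'   space; default [default_priors()].
#' @param n_restarts Number of optimizer restarts (default 8).
#' @param seed Integer seed for the restart draws.
#' @param kappa Fixed level-3 to level-2 coupling (default 1).
#' @return An object of class `hgfs_fit`: MAP estimates in native and
#'   unconstrained space, `log_joint`, `log_lik`, `log_evidence` (with
#'   `evidence_method` `"laplace"` or `"bic"`), Hessian diagnostics,
#'   `converged` flag, restart log-joints, and the belief trajectory at the
#'   MAP. Use [tidy()] / [glance()] to extract tibbles.
#' @export
fit_map <- function(data, model = c("hgfs", "hgf", "rw", "sk1"),
                    priors = NULL, n_restarts = 8, seed = 1L, kappa = 1) {
  model <- match.arg(model)
  if (is.null(priors)) priors <- default_priors(model)
  free <- model_free_params(model)
  abort_if(!all(free %in% names(priors)),
           paste("priors must cover:", paste(free, collapse = ", ")))
  if (nrow(data) > 0) {
    require_columns(data, c("u", "y"), "data")
    if (model == "hgfs") require_columns(data, "congruent", "data")
  }

  prior_mean <- vapply(priors[free], `[`, double(1), 1)
  names(prior_mean) <- free
  objective <- function(theta) {
    names(theta) <- free
    lj <- log_joint_at(theta, data, model, priors, kappa)
    if (!is.finite(lj)) 1e12 else -lj
  }

  starts <- with_seed(derive_seed(seed, 7L), {
    extra <- lapply(seq_len(max(0, n_restarts - 1)), function(i) {
      vapply(free, function(nm) {
        stats::rnorm(1, priors[[nm]][1], priors[[nm]][2])
      }, double(1))
    })
    c(list(prior_mean), extra)
  })

  fits <- lapply(starts, function(s) {
    tryCatch(
      stats::optim(s, objective, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
  })
  vals <- vapply(fits, function(f) {
    if (is.null(f) || !is.finite(f$value) || f$value >= 1e11) Inf else f$value
  }, double(1))

  if (all(!is.finite(vals))) {
    return(structure(list(
      model = model, estimates = NULL, theta = NULL, log_joint = -Inf,
      log_lik = -Inf, log_evidence = -Inf, evidence_method = "failed",
      converged = FALSE, failed = TRUE, n_restarts_used = length(starts),
      restart_log_joints = -vals, n_trials = nrow(data), priors = priors,
      trajectory = NULL, seed = seed
    ), class = "hgfs_fit"))
  }

  best <- which.min(vals)
  theta <- fits[[best]]$par
  # Polish: BFGS restarts from the incumbent reset the Hessian approximation
  # and sharpen the optimum until the log joint stops moving.
  val <- fits[[best]]$value
  for (pol in 1:3) {
    polish <- tryCatch(
      stats::optim(theta, objective, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-14,
                                  ndeps = rep(1e-7, length(theta)))),
      error = function(e) NULL
    )
    if (is.null(polish) || !is.finite(polish$value) || polish$value > val)
      break
    improved <- val - polish$value
    theta <- polish$par
    val <- polish$value
    if (improved < 1e-10) break
  }
  names(theta) <- free
  log_joint <- -val
  native <- to_native(theta, model)

  lj_fun <- function(x) { names(x) <- free; log_joint_at(x, data, model, priors, kappa) }
  grad <- numeric_gradient(lj_fun, theta)
  sorted <- sort(vals[is.finite(vals)])
  agree <- length(sorted) < 2 || (sorted[2] - sorted[1]) < 1e-3 ||
    n_restarts == 1
  converged <- sqrt(sum(grad^2)) < 1e-5 && agree

  d <- length(theta)
  hess <- tryCatch(stats::optimHess(theta, objective), error = function(e) NULL)
  chol_ok <- !is.null(hess) &&
    !inherits(try(chol(hess), silent = TRUE), "try-error")
  ll <- log_joint - sum(vapply(free, function(nm) {
    stats::dnorm(theta[[nm]], priors[[nm]][1], priors[[nm]][2], log = TRUE)
  }, double(1)))
  if (chol_ok) {
    log_evidence <- log_joint + (d / 2) * log(2 * pi) -
      0.5 * determinant(hess, logarithm = TRUE)$modulus[1]
    evidence_method <- "laplace"
  } else {
    log_evidence <- ll - (d / 2) * log(max(nrow(data), 1))
    evidence_method <- "bic"
  }

  trajectory <- if (nrow(data) > 0) {
    switch(model,
      hgfs = filter_hgfs(data, hgfs_params(native$omega2, native$omega3,
                                           native$tau, kappa = kappa)),
      hgf = filter_hgfs(data, hgfs_params(native$omega2, native$omega3,
                                          tau = 0, kappa = kappa),
                        social_noise = FALSE),
      rw = filter_rw(data, native$alpha),
      sk1 = filter_sk1(data, native$mu_meta)
    )
  } else NULL

  structure(list(
    model = model, estimates = native, theta = theta, log_joint = log_joint,
    log_lik = ll, log_evidence = as.numeric(log_evidence),
    evidence_method = evidence_method, hessian = hess,
    hessian_pd = chol_ok, gradient_norm = sqrt(sum(grad^2)),
    converged = converged, failed = FALSE,
    n_restarts_used = length(starts), restart_log_joints = -vals,
    n_trials = nrow(data), priors = priors, trajectory = trajectory,
    seed = seed
  ), class = "hgfs_fit")
}

#' Log model evidence of a fit
#'
#' Returns the Laplace-approximate log model evidence stored in an
#' [fit_map()] result (`-Inf` for a failed fit).
#'
#' @param fit An `hgfs_fit` object.
#' @return A scalar log evidence.
#' @export
log_model_evidence <- function(fit) {
  abort_if(!inherits(fit, "hgfs_fit"), "fit must be an hgfs_fit")
  fit$log_evidence
}

#' @export
print.hgfs_fit <- function(x, ...) {
  cat(sprintf("<hgfs_fit: %s, %d trials>\n", x$model, x$n_trials))
  if (x$failed) {
    cat("  all restarts failed\n")
    return(invisible(x))
  }
  est <- vapply(x$estimates, identity, double(1))
  cat("  MAP estimates (native):",
      paste(sprintf("%s = %.4g", names(est), est), collapse = ", "), "\n")
  cat(sprintf("  log joint %.3f | log evidence %.3f (%s) | converged: %s\n",
              x$log_joint, x$log_evidence, x$evidence_method, x$converged))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Simulates cohorts from known population parameters, refits the
#' generating model to every agent, and tabulates generating versus
#' recovered values in each parameter's unconstrained space. Use
#' [recovery_summary()] for per-parameter Pearson/Spearman correlations and
#' bias, and the `recovered_cor` attribute for the pairwise correlations
#' among recovered parameters.
#'
#' @param schedule Trial schedule from [generate_schedule()].
#' @param spec A [cohort_spec()]; its `model` is both the generating and the
#'   refitted model.
#' @param n_reps Number of independent simulate-and-refit repetitions.
#' @param seed Master seed.
#' @param rep_seeds Optional explicit integer seed per repetition
#'   (overrides derivation from `seed`).
#' @param priors,n_restarts Passed to [fit_map()].
#' @return A tibble with columns `rep`, `subject`, `parameter`
#'   (unconstrained-space name), `true`, `recovered`, `converged`;
#'   attribute `recovered_cor` holds the correlation matrix among recovered
#'   parameters.
#' @export
parameter_recovery <- function(schedule, spec = cohort_spec(), n_reps = 1,
                               seed = 1L, rep_seeds = NULL, priors = NULL,
                               n_restarts = 8) {
  if (is.null(rep_seeds)) {
    rep_seeds <- vapply(seq_len(n_reps), function(r) derive_seed(seed, 31L, r),
                        integer(1))
  }
  abort_if(length(rep_seeds) != n_reps, "rep_seeds must have length n_reps")
  free <- model_free_params(spec$model)

  rows <- purrr::map2_dfr(seq_len(n_reps), rep_seeds, function(r, rs) {
    cohort <- simulate_cohort(schedule, spec, seed = rs)
    purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      dat <- cohort$data[[i]]
      true_nat <- attr(dat, "params")
      true_u <- native_to_unconstrained(true_nat, spec$model)
      fit <- fit_map(dat, model = spec$model, priors = priors,
                     n_restarts = n_restarts, seed = derive_seed(rs, 41L, i))
      rec <- if (fit$failed) stats::setNames(rep(NA_real_, length(free)), free)
        else fit$theta
      tibble::tibble(rep = r, subject = i, parameter = free,
                     true = unname(true_u[free]), recovered = unname(rec[free]),
                     converged = !fit$failed && fit$converged)
    })
  })

  wide <- tidyr::pivot_wider(rows[, c("rep", "subject", "parameter", "recovered")],
                             names_from = "parameter", values_from = "recovered")
  rec_mat <- as.matrix(wide[, free, drop = FALSE])
  attr(rows, "recovered_cor") <- if (nrow(rec_mat) >= 3) {
    stats::cor(rec_mat, use = "pairwise.complete.obs")
  } else NULL
  rows
}

# Correlation that returns NA (not a warning) for zero-variance inputs,
# e.g. a population parameter held fixed in the generating spec.
safe_cor <- function(x, y, method = "pearson") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

# Native parameter list -> named unconstrained vector.
native_to_unconstrained <- function(native, model) {
  out <- switch(model,
    hgfs = c(omega2 = native$omega2, omega3 = native$omega3,
             tau = native$tau, log_zeta = log(native$zeta)),
    hgf = c(omega2 = native$omega2, omega3 = native$omega3,
            log_zeta = log(native$zeta)),
    rw = c(logit_alpha = stats::qlogis(native$alpha),
           log_zeta = log(native$zeta)),
    sk1 = c(log_mu_meta = log(native$mu_meta), log_zeta = log(native$zeta))
  )
  out
}

#' Summarize a parameter-recovery table
#'
#' Per-parameter Pearson and Spearman correlations between generating and
#' recovered values, plus mean bias (recovered minus true).
#'
#' @param recovery A tibble from [parameter_recovery()].
#' @return A tibble with columns `parameter`, `n`, `pearson`, `spearman`,
#'   `bias`.
#' @export
recovery_summary <- function(recovery) {
  require_columns(recovery, c("parameter", "true", "recovered"), "recovery")
  recovery |>
    dplyr::filter(is.finite(.data$recovered)) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      n = dplyr::n(),
      pearson = safe_cor(.data$true, .data$recovered),
      spearman = safe_cor(.data$true, .data$recovered, method = "spearman"),
      bias = mean(.data$recovered - .data$true),
      .groups = "drop"
    )
}
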