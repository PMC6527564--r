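test_that("zero-information data returns the prior with zero evidence", {
  empty <- tibble::tibble(u = integer(), y = integer(), congruent = logical())
  fit <- fit_map(empty, "hgfs", n_restarts = 2, seed = 1)
  pr <- default_priors("hgfs")
  expect_equal(fit$theta[["omega2"]], pr$omega2[1], tolerance = 1e-4)
  expect_equal(fit$theta[["tau"]], pr$tau[1], tolerance = 1e-4)
  expect_equal(fit$estimates$zeta, exp(pr$log_zeta[1]), tolerance = 1e-3)
  # Laplace is exact for a Gaussian log-joint: evidence = 0 likelihood mass
  expect_equal(fit$log_evidence, 0, tolerance = 1e-5)
})

test_that("the MAP dominates the generating parameters on simulated data", {
  sched <- generate_schedule(seed = 2)
  env <- simulate_environment(sched, seed = 3)
  gen <- list(omega2 = -3, omega3 = -4, tau = 1, zeta = 5)
  dat <- simulate_subject(env, "hgfs", gen, seed = 4)
  fit <- fit_map(dat, "hgfs", seed = 5)
  pr <- fit$priors
  theta_gen <- c(omega2 = -3, omega3 = -4, tau = 1, log_zeta = log(5))
  lj_gen <- socialnoise:::log_joint_at(theta_gen, dat, "hgfs", pr)
  expect_gte(fit$log_joint, lj_gen)
  expect_true(fit$converged)
  expect_s3_class(fit$trajectory, "hgfs_trajectory")
})

test_that("fits are deterministic given the seed", {
  sched <- generate_schedule(pal_blocks()[1:3, ], seed = 6)
  env <- simulate_environment(sched, seed = 7)
  dat <- simulate_subject(env, "rw", list(alpha = 0.3, zeta = 8), seed = 8)
  a <- fit_map(dat, "rw", n_restarts = 4, seed = 11)
  b <- fit_map(dat, "rw", n_restarts = 4, seed = 11)
  expect_identical(a$theta, b$theta)
  expect_identical(a$log_evidence, b$log_evidence)
})

test_that("an irrelevant pinned parameter leaves the evidence unchanged", {
  # on an all-congruent dataset tau never enters the likelihood, and with a
  # near-degenerate prior its Laplace contribution cancels exactly
  sched <- generate_schedule(pal_blocks()[c(1, 3), ], seed = 9)
  env <- simulate_environment(sched, seed = 10)
  dat <- simulate_subject(env, "hgf", list(omega2 = -3, omega3 = -4,
                                           zeta = 10), seed = 11)
  dat$congruent <- TRUE
  pr_s <- default_priors("hgfs")
  pr_s$tau <- c(0, 1e-4)
  fit_s <- fit_map(dat, "hgfs", priors = pr_s, n_restarts = 3, seed = 12)
  fit_0 <- fit_map(dat, "hgf", n_restarts = 3, seed = 12)
  expect_equal(fit_s$log_evidence, fit_0$log_evidence, tolerance = 1e-4)
})

test_that("tau is recoverable from strong-noise simulations", {
  sched <- generate_schedule(seed = 13)
  gen <- list(omega2 = -3, omega3 = -4, tau = 1, zeta = 20)
  hits <- 0
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    env <- simulate_environment(sched, seed = 100 + s)
    dat <- simulate_subject(env, "hgfs", gen, seed = 200 + s)
    fit <- fit_map(dat, "hgfs", n_restarts = 4, seed = 300 + s)
    # recovered tau closer to the generating value than to the prior mean 0
    if (abs(fit$estimates$tau - 1) < abs(0 - 1)) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.7)
})

test_that("parameter recovery tabulates generating vs refitted values", {
  sched <- generate_schedule(seed = 14)
  spec <- cohort_spec(n_subjects = 4, model = "rw",
                      logit_alpha = c(0, 0.7), log_zeta = c(log(10), 0.3))
  rec <- parameter_recovery(sched, spec, n_reps = 1, seed = 15,
                            n_restarts = 3)
  expect_equal(nrow(rec), 4 * 2)  # 4 subjects x 2 free parameters
  expect_true(all(c("logit_alpha", "log_zeta") %in% rec$parameter))
  summ <- recovery_summary(rec)
  expect_true(all(is.finite(summ$pearson)))
  # identical repetition seeds give identical rows
  rec2 <- parameter_recovery(sched, spec, n_reps = 2, seed = 15,
                             rep_seeds = c(77, 77), n_restarts = 2)
  r1 <- rec2[rec2$rep == 1, -1]
  r2 <- rec2[rec2$rep == 2, -1]
  expect_identical(r1, r2)
})

test_that("tidy and glance expose fit results", {
  empty <- tibble::tibble(u = integer(), y = integer(), congruent = logical())
  fit <- fit_map(empty, "rw", n_restarts = 2, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_named(td, c("parameter", "estimate", "unconstrained"))
  gl <- glance(fit)
  expect_equal(gl$model, "rw")
  expect_identical(log_model_evidence(fit), gl$log_evidence)
})
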