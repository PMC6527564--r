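test_that("decision-change table reproduces a hand-enumerated toy case", {
  # four low-uncertainty pairs, one per cell, with changes 1,0,0,1:
  # SN_d = (1 - 0) - (0 - 1) = 2, the analytic maximum
  dat <- make_dc_data(
    correct = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    congruent = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    changed = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    label = c("low", "high", "low", "high", "low", "high", "low", "high")
  )
  tab <- decision_change_table(dat)
  low <- tab[tab$condition == "low", ]
  expect_equal(low$dc_wc, 1)
  expect_equal(low$dc_wi, 0)
  expect_equal(low$dc_cc, 0)
  expect_equal(low$dc_ci, 1)
  expect_equal(low$snd, 2)
  expect_equal(low$n_wc + low$n_wi + low$n_cc + low$n_ci, 4)
})

test_that("equal change ratios give a vanishing interaction", {
  # every cell observed twice with exactly one change: all ratios 0.5
  cells <- expand.grid(correct = c(FALSE, TRUE), congruent = c(FALSE, TRUE),
                       rep = 1:2)
  dat <- make_dc_data(correct = cells$correct, congruent = cells$congruent,
                      changed = cells$rep == 1,
                      label = rep("low", nrow(cells)))
  low <- decision_change_table(dat)[1, ]
  expect_equal(low$dc_wc, 0.5)
  expect_equal(low$snd, 0)
})

test_that("empty cells propagate as undefined, never as zero", {
  dat <- tibble::tibble(
    y = c(0L, 1L, 1L, 0L),
    correct = TRUE,                       # no wrong-choice trials at all
    congruent = c(TRUE, FALSE, TRUE, FALSE),
    uncertainty_label = "low"
  )
  low <- decision_change_table(dat)[1, ]
  expect_true(is.na(low$dc_wc))
  expect_true(is.na(low$dc_wi))
  expect_true(is.na(low$snd))
  expect_equal(low$n_wc, 0)
  expect_equal(low$n_cc + low$n_ci, 3)
  expect_error(decision_change_table(dat[1, ]), "2 trials")
})

test_that("SN_d is antisymmetric under congruency relabelling", {
  set.seed(31)
  for (i in 1:5) {
    n <- 60
    dat <- tibble::tibble(
      y = sample(0:1, n, replace = TRUE),
      correct = sample(c(TRUE, FALSE), n, replace = TRUE),
      congruent = sample(c(TRUE, FALSE), n, replace = TRUE),
      uncertainty_label = sample(c("low", "high"), n, replace = TRUE)
    )
    flipped <- dat
    flipped$congruent <- !flipped$congruent
    a <- decision_change_table(dat)
    b <- decision_change_table(flipped)
    expect_equal(b$snd, -a$snd, tolerance = 1e-12)
  }
})

test_that("cue-matched pairing differs but preserves the cell accounting", {
  set.seed(17)
  n <- 80
  dat <- tibble::tibble(
    cue = sample(c("high", "low"), n, replace = TRUE),
    y = sample(0:1, n, replace = TRUE),
    correct = sample(c(TRUE, FALSE), n, replace = TRUE),
    congruent = sample(c(TRUE, FALSE), n, replace = TRUE),
    uncertainty_label = "low"
  )
  plain <- decision_change_table(dat)
  matched <- decision_change_table(dat, cue_matched = TRUE)
  expect_equal(plain$n_wc[1] + plain$n_wi[1] + plain$n_cc[1] +
                 plain$n_ci[1], n - 1)
  # cue-matched pairing drops trailing trials without a same-cue successor
  expect_lte(matched$n_wc[1] + matched$n_wi[1] + matched$n_cc[1] +
               matched$n_ci[1], n - 1)
})

test_that("one-sample group test of SN_d", {
  z <- snd_group_test(rep(0, 10))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_equal(snd_group_test(c(1, -1))$t, 0)
  g <- snd_group_test(c(0.2, 0.4, 0.6))
  expect_equal(g$t, 0.4 / (0.2 / sqrt(3)), tolerance = 1e-6)
  expect_equal(g$df, 2)
  withNA <- snd_group_test(c(0.2, 0.4, 0.6, NA))
  expect_equal(withNA$n_excluded, 1)
  expect_equal(withNA$n, 3)
})

test_that("tau-SN_d association uses Spearman ranks", {
  expect_equal(tau_snd_correlation(1:6, (1:6)^3)$rho, 1)
  expect_equal(tau_snd_correlation(1:6, -(1:6)^3)$rho, -1)
  expect_equal(tau_snd_correlation(c(1, 2, 3), c(2, 1, 3))$rho, 0.5,
               tolerance = 1e-9)
  expect_error(tau_snd_correlation(1:2, 1:2), "3 complete")
})

test_that("a null perturbation reproduces the original arm exactly", {
  sched <- generate_schedule(pal_blocks()[1:2, ], seed = 3)
  fits <- data.frame(omega2 = c(-3, -2.5), omega3 = -4, tau = -1, zeta = 20)
  pert <- tau_perturbation_experiment(fits, sched, delta_tau = 0,
                                      n_reps = 3, seed = 5)
  expect_identical(pert$subjects$fluct1_orig, pert$subjects$fluct1_pert)
  expect_identical(pert$subjects$fluct3_orig, pert$subjects$fluct3_pert)
  expect_identical(pert$subjects$snd_low_orig, pert$subjects$snd_low_pert)
  expect_equal(glance(pert)$delta_tau, 0)
})
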