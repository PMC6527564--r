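test_that("logistic is the increasing unit sigmoid", {
  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(1), 0.7310586, tolerance = 1e-7)
  expect_equal(logistic(1e4), 1)
  expect_true(all(diff(logistic(seq(-5, 5, 0.5))) > 0))
})

test_that("level-1 posterior matches the two-Gaussian Bayes rule", {
  # direct density-ratio oracle
  oracle <- function(u, m, tau) {
    sdv <- sqrt(exp(tau) / 2)
    num <- dnorm(u, 1, sdv) * m
    num / (num + dnorm(u, 0, sdv) * (1 - m))
  }
  grid <- expand.grid(u = c(0, 1), m = c(0.05, 0.3, 0.5, 0.8, 0.95),
                      tau = c(-3, -1, 0, 1, 3))
  got <- with(grid, level1_posterior(u, m, tau))
  want <- with(grid, oracle(u, m, tau))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(level1_posterior(1, 0.5, 0), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
})

test_that("level-1 posterior limits and monotonicity in tau", {
  # vanishing noise recovers mu1 = u; infinite noise stops learning
  expect_equal(level1_posterior(1, 0.3, -50), 1)
  expect_equal(level1_posterior(0, 0.3, -50), 0)
  expect_equal(level1_posterior(1, 0.3, 60), 0.3, tolerance = 1e-9)
  # strictly decreasing in tau for u = 1, and always between prior and input
  taus <- seq(-3, 4, 0.5)
  vals <- level1_posterior(rep(1, length(taus)), 0.4, taus)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0.4 & vals < 1))
  v0 <- level1_posterior(rep(0, length(taus)), 0.4, taus)
  expect_true(all(v0 > 0 & v0 < 0.4))
  expect_error(level1_posterior(1, 1, 0), "degenerate")
})

test_that("social noise attenuates but never flips the level-1 prediction error", {
  for (m in c(0.2, 0.5, 0.8)) for (tau in c(-2, 0, 2)) {
    noiseless <- 1 - m
    noisy <- level1_posterior(1, m, tau) - m
    expect_gt(noisy, 0)
    expect_gte(noiseless, noisy)
  }
})

test_that("hgf_step honours the noiseless level-1 rule and freezes on zero error", {
  p <- hgfs_params(omega2 = -2, omega3 = -4, tau = 0)
  state <- list(mu2 = 0.3, sigma2 = 0.2, mu3 = 1, sigma3 = 0.5)
  up <- hgf_step(state, 1, FALSE, p)
  expect_identical(up$mu1, 1)
  expect_equal(up$delta1, 1 - plogis(0.3))

  # mu1 == muhat1 leaves the tendency unchanged
  mh <- plogis(state$mu2)
  fake_u <- mh  # continuous input equal to the prediction: delta1 = 0
  up0 <- hgf_step(state, fake_u, FALSE, p)
  expect_equal(up0$delta1, 0)
  expect_equal(up0$mu2, state$mu2)
})

test_that("HGF-S with vanishing noise reduces to the HGF", {
  dat <- fixture_20_data()
  p_noisy <- hgfs_params(omega2 = -2.5, omega3 = -5, tau = -30)
  p_plain <- hgfs_params(omega2 = -2.5, omega3 = -5, tau = 0)
  noisy <- filter_hgfs(dat, p_noisy, social_noise = TRUE)
  plain <- filter_hgfs(dat, p_plain, social_noise = FALSE)
  for (col in c("muhat1", "mu1", "mu2", "sigma2", "mu3", "sigma3")) {
    expect_equal(noisy[[col]], plain[[col]], tolerance = 1e-9)
  }
})

test_that("an all-congruent dataset makes HGF-S and HGF identical", {
  dat <- fixture_20_data()
  dat$congruent <- TRUE
  p <- hgfs_params(omega2 = -3, omega3 = -4, tau = 1)
  a <- filter_hgfs(dat, p, social_noise = TRUE)
  b <- filter_hgfs(dat, p, social_noise = FALSE)
  expect_equal(a$mu2, b$mu2)
  expect_equal(a$mu3, b$mu3)
})

test_that("filter trajectories match an independent transcription of the updates", {
  fx <- fixture_20()
  for (tau in c(-1, 0.5, 2)) {
    p <- hgfs_params(omega2 = -2.8, omega3 = -4.2, tau = tau)
    got <- filter_hgfs(tibble::tibble(u = fx$u, congruent = fx$congruent), p)
    want <- oracle_hgfs_filter(fx$u, !fx$congruent, -2.8, -4.2, tau)
    for (col in names(want)) {
      expect_equal(got[[col]], want[[col]], tolerance = 1e-9,
                   label = paste0(col, " (tau=", tau, ")"))
    }
  }
})

test_that("first-trial prediction is 0.5 under default initial beliefs", {
  tr <- filter_hgfs(tibble::tibble(u = 1, congruent = TRUE), hgfs_params())
  expect_equal(tr$muhat1, 0.5)
  expect_equal(nrow(tr), 1)
})

test_that("Rescorla-Wagner follows the delta rule", {
  expect_equal(filter_rw(tibble::tibble(u = 1), alpha = 0.5)$value, 0.75)
  # tiny alpha keeps the value near v0
  traj <- filter_rw(tibble::tibble(u = rep(1, 50)), alpha = 1e-6)
  expect_true(all(abs(traj$value - 0.5) < 1e-4))
  # constant input converges monotonically toward it
  mono <- filter_rw(tibble::tibble(u = rep(1, 50)), alpha = 0.3)
  expect_true(all(diff(mono$value) > 0))
  expect_lt(max(mono$value), 1)
  expect_error(filter_rw(tibble::tibble(u = 1), alpha = 1.5), "alpha")
})

test_that("Sutton K1 adapts its gain to prediction-error correlation", {
  u_alt <- tibble::tibble(u = rep(c(1L, 0L), 25))
  # zero meta-learning reduces exactly to RW with alpha = logistic(beta0)
  sk <- filter_sk1(u_alt, mu_meta = 0, beta0 = qlogis(0.3))
  rw <- filter_rw(u_alt, alpha = 0.3)
  expect_equal(sk$value, rw$value, tolerance = 1e-12)
  # alternating inputs decorrelate errors and shrink the gain
  sk2 <- filter_sk1(u_alt, mu_meta = 0.5)
  expect_lt(sk2$alpha[nrow(sk2)], sk2$alpha[1])
  # a consistent run of identical inputs grows it
  sk3 <- filter_sk1(tibble::tibble(u = rep(1L, 30)), mu_meta = 0.5)
  expect_true(all(diff(sk3$alpha) >= 0))
})

test_that("belief fluctuation is total variation of the trajectory", {
  tr <- tibble::tibble(mu1 = c(0.5, 0.7311, 0.6), mu2 = c(1, 1, 1),
                       mu3 = c(0, 1, 0))
  expect_equal(belief_fluctuation(tr, 1), 0.3622, tolerance = 1e-4)
  expect_equal(belief_fluctuation(tr, 2), 0)
  expect_equal(belief_fluctuation(tr, 3), 2)
  rev_tr <- tr[3:1, ]
  expect_equal(belief_fluctuation(rev_tr, 1), belief_fluctuation(tr, 1))
  expect_error(belief_fluctuation(tr[1, ], 1), "2 trials")
})
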