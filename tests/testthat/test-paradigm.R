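test_that("default schedule has the printed block structure", {
  sched <- generate_schedule(seed = 7)
  expect_equal(nrow(sched), 300)
  expect_equal(sum(sched$uncertainty_label == "low"), 150)
  expect_equal(sum(sched$uncertainty_label == "high"), 150)
  expect_equal(length(unique(sched$block_id)), 10)
  # p_assoc constant within block, every trial labelled exactly once
  per_block <- tapply(sched$p_assoc, sched$block_id, function(x) length(unique(x)))
  expect_true(all(per_block == 1))
  expect_true(all(sched$uncertainty_label %in% c("low", "high")))
})

test_that("schedule generation validates inputs and handles empty blocks", {
  expect_equal(nrow(generate_schedule(data.frame(n_trials = integer(),
                                                 p_assoc = double()))), 0)
  expect_error(generate_schedule(data.frame(n_trials = 10, p_assoc = 1.2)),
               "p_assoc")
})

test_that("schedule and environment are pure functions of the seed", {
  a <- simulate_environment(generate_schedule(seed = 3), seed = 5)
  b <- simulate_environment(generate_schedule(seed = 3), seed = 5)
  expect_identical(a, b)
  c <- simulate_environment(generate_schedule(seed = 3), seed = 6)
  expect_false(identical(a$u, c$u))
})

test_that("environment outcomes follow the contingency", {
  # degenerate probabilities are deterministic
  s1 <- data.frame(trial_index = 1:20, block_id = 1, cue = "high",
                   p_assoc = 1, uncertainty_label = "low",
                   face_valence = "happy")
  e1 <- simulate_environment(s1, seed = 1)
  expect_true(all(e1$outcome_gender == "female"))
  s0 <- transform(s1, cue = "low", p_assoc = 0)
  e0 <- simulate_environment(s0, seed = 1)
  expect_true(all(e0$u == 0))
  expect_true(all(e0$outcome_gender == "female"))

  # a long p = 0.9 block concentrates u near 0.9 (3 binomial SEs)
  big <- generate_schedule(data.frame(n_trials = 4000, p_assoc = 0.9),
                           seed = 2)
  eb <- simulate_environment(big, seed = 2)
  se <- sqrt(0.9 * 0.1 / 4000)
  expect_lt(abs(mean(eb$u) - 0.9), 3 * se)

  # and p = 0.5 stays within the 3-sigma band
  half <- generate_schedule(data.frame(n_trials = 10000, p_assoc = 0.5),
                            seed = 3)
  eh <- simulate_environment(half, seed = 3)
  expect_gt(mean(eh$u), 0.485)
  expect_lt(mean(eh$u), 0.515)
})

test_that("encode_trials applies the contingency coding and congruency rule", {
  row <- function(cue, out, cho, val) {
    data.frame(cue = cue, outcome_gender = out, choice_gender = cho,
               face_valence = val)
  }
  a <- encode_trials(row("high", "female", "female", "happy"))
  expect_equal(a$u, 1L); expect_equal(a$y, 1L)
  expect_true(a$correct); expect_true(a$congruent)

  # a correct answer paired with a sad face is emotionally incongruent
  b <- encode_trials(row("high", "female", "female", "sad"))
  expect_true(b$correct); expect_false(b$congruent)

  c <- encode_trials(row("low", "female", "male", "happy"))
  expect_equal(c$u, 0L); expect_equal(c$y, 1L)
  expect_false(c$correct); expect_false(c$congruent)

  expect_error(encode_trials(row("mid", "female", "male", "happy")), "row")
  expect_error(encode_trials(data.frame(cue = "high")), "missing")
})

test_that("face valence is independent of performance: congruent fraction near 1/2", {
  sched <- generate_schedule(seed = 11)
  fracs <- vapply(1:10, function(s) {
    env <- simulate_environment(sched, seed = s)
    sub <- simulate_subject(env, "hgfs",
                            list(omega2 = -3, omega3 = -4, tau = -1,
                                 zeta = 20), seed = s + 100)
    mean(sub$congruent)
  }, double(1))
  expect_lt(abs(mean(fracs) - 0.5), 0.03)
})

test_that("cohort simulation is reproducible and handles degenerate sizes", {
  sched <- generate_schedule(seed = 1)
  spec <- cohort_spec(n_subjects = 3)
  a <- simulate_cohort(sched, spec, seed = 9)
  b <- simulate_cohort(sched, spec, seed = 9)
  expect_identical(a$data, b$data)
  expect_equal(nrow(simulate_cohort(sched, cohort_spec(n_subjects = 0))), 0)
})

test_that("noise-free accurate agents do better under low irreducible uncertainty", {
  sched <- generate_schedule(seed = 2)
  spec <- cohort_spec(n_subjects = 20, model = "hgfs", tau = c(-20, 0),
                      omega2 = c(-3, 0.3), omega3 = c(-4, 0.3),
                      log_zeta = c(log(48), 0))
  coh <- simulate_cohort(sched, spec, seed = 5)
  acc <- purrr::map_dfr(coh$data, function(d) {
    tibble::tibble(low = mean(d$correct[d$uncertainty_label == "low"]),
                   high = mean(d$correct[d$uncertainty_label == "high"]))
  })
  expect_gt(mean(acc$low), mean(acc$high))
  expect_gt(mean(acc$low > acc$high), 0.9)
})
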