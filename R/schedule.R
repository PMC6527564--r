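#' Default PAL-S block structure
#'
#' The default probabilistic associative learning task runs 300 trials in 10
#' blocks of 30. The cue--outcome contingency p(F|HT) alternates between
#' near-deterministic blocks (p of 0.9 or 0.1, low irreducible uncertainty)
#' and near-chance blocks (p of 0.45 or 0.55, high irreducible uncertainty),
#' so that exactly 150 trials fall in each uncertainty regime.
#'
#' @return A tibble with columns `n_trials` and `p_assoc`, one row per block.
#' @export
#' @examples
#' pal_blocks()
pal_blocks <- function() {
  tibble::tibble(
    n_trials = rep(30L, 10),
    p_assoc  = c(0.9, 0.45, 0.1, 0.55, 0.9, 0.45, 0.1, 0.55, 0.9, 0.45)
  )
}

#' Generate a PAL-S trial schedule
#'
#' Builds the per-trial environment for the task: block-wise true association
#' probability, an i.i.d. 50/50 cue sequence, a pre-assigned 50/50 happy/sad
#' face valence sequence that is independent of cue, contingency, and any
#' outcome, and an irreducible-uncertainty label per trial. A block counts as
#' low irreducible uncertainty when its contingency is at least
#' `label_threshold` away from chance.
#'
#' @param blocks A data frame with columns `n_trials` and `p_assoc`
#'   (default [pal_blocks()]). An empty block list yields an empty schedule.
#' @param seed Integer seed; the schedule is a pure function of
#'   `(blocks, seed, label_threshold)`.
#' @param label_threshold Distance from 0.5 at or beyond which a block is
#'   labelled `"low"` irreducible uncertainty. Default 0.3.
#' @return A tibble with one row per trial and columns `trial_index`,
#'   `block_id`, `cue` (`"high"`/`"low"` tone), `p_assoc`,
#'   `uncertainty_label` (`"low"`/`"high"`), `face_valence`
#'   (`"happy"`/`"sad"`).
#' @export
#' @examples
#' sched <- generate_schedule(seed = 1)
#' table(sched$uncertainty_label)
generate_schedule <- function(blocks = pal_blocks(), seed = 1L,
                              label_threshold = 0.3) {
  blocks <- tibble::as_tibble(blocks)
  if (nrow(blocks) == 0) {
    return(tibble::tibble(
      trial_index = integer(), block_id = integer(), cue = character(),
      p_assoc = double(), uncertainty_label = character(),
      face_valence = character()
    ))
  }
  require_columns(blocks, c("n_trials", "p_assoc"), "blocks")
  abort_if(any(blocks$p_assoc < 0 | blocks$p_assoc > 1),
           "p_assoc must lie in [0, 1]")
  abort_if(any(blocks$n_trials < 0), "n_trials must be non-negative")

  n <- sum(blocks$n_trials)
  sched <- tibble::tibble(
    trial_index = seq_len(n),
    block_id = rep(seq_len(nrow(blocks)), blocks$n_trials),
    p_assoc = rep(blocks$p_assoc, blocks$n_trials)
  )
  sched$uncertainty_label <-
    ifelse(abs(sched$p_assoc - 0.5) >= label_threshold, "low", "high")
  with_seed(derive_seed(seed, 101L), {
    sched$cue <- sample(c("high", "low"), n, replace = TRUE)
    sched$face_valence <- sample(c("happy", "sad"), n, replace = TRUE)
  })
  sched[, c("trial_index", "block_id", "cue", "p_assoc",
            "uncertainty_label", "face_valence")]
}

#' Simulate task outcomes for a schedule
#'
#' Draws one session's realization of the environment: the contingency-coded
#' outcome `u ~ Bernoulli(p_assoc)` per trial (`u = 1` means the association
#' held -- female after a high tone, or male after a low tone) and, by
#' default, a fresh 50/50 face-valence stream. Each simulated session gets
#' its own independent face randomization, as at the task's runtime; keep
#' `resample_valence = FALSE` to retain the schedule's pre-assigned valence
#' sequence (e.g. to reproduce one specific recorded session).
#'
#' @param schedule A schedule tibble from [generate_schedule()].
#' @param seed Integer seed for the outcome (and valence) streams.
#' @param resample_valence Redraw `face_valence` for this session? Default
#'   `TRUE`.
#' @return The schedule with added columns `u` (0/1) and `outcome_gender`
#'   (`"female"`/`"male"`).
#' @export
simulate_environment <- function(schedule, seed = 1L,
                                 resample_valence = TRUE) {
  require_columns(schedule, c("cue", "p_assoc"), "schedule")
  n <- nrow(schedule)
  u <- with_seed(derive_seed(seed, 202L),
                 as.integer(stats::runif(n) < schedule$p_assoc))
  if (resample_valence) {
    schedule$face_valence <- with_seed(
      derive_seed(seed, 203L),
      sample(c("happy", "sad"), n, replace = TRUE))
  }
  schedule$u <- u
  schedule$outcome_gender <-
    ifelse((schedule$cue == "high") == (u == 1L), "female", "male")
  schedule
}

#' Encode raw trials into model inputs
#'
#' Maps recorded per-trial cues, outcomes, choices and face valences into the
#' contingency coding used by the learning models: `u = 1` iff the
#' association held (high tone followed by female, or low tone by male), `y`
#' coded identically from the choice, `correct = (y == u)`, and
#' `congruent = (correct & happy) | (!correct & sad)` -- an emotionally
#' congruent feedback pairs a happy face with a correct answer or a sad face
#' with an incorrect one.
#'
#' @param raw A data frame with columns `cue` (`"high"`/`"low"`),
#'   `outcome_gender`, `choice_gender` (`"female"`/`"male"`), and
#'   `face_valence` (`"happy"`/`"sad"`).
#' @return The input tibble with added columns `u`, `y`, `correct`,
#'   `congruent`.
#' @export
#' @examples
#' encode_trials(data.frame(
#'   cue = "high", outcome_gender = "female",
#'   choice_gender = "female", face_valence = "sad"
#' ))
encode_trials <- function(raw) {
  raw <- tibble::as_tibble(raw)
  require_columns(raw, c("cue", "outcome_gender", "choice_gender",
                         "face_valence"), "raw trials")
  check_levels <- function(col, levels) {
    bad <- which(!raw[[col]] %in% levels)
    abort_if(length(bad) > 0,
             sprintf("column '%s' has invalid entries at row(s) %s (allowed: %s)",
                     col, paste(utils::head(bad, 5), collapse = ", "),
                     paste(levels, collapse = "/")))
  }
  check_levels("cue", c("high", "low"))
  check_levels("outcome_gender", c("female", "male"))
  check_levels("choice_gender", c("female", "male"))
  check_levels("face_valence", c("happy", "sad"))

  raw$u <- as.integer((raw$cue == "high") == (raw$outcome_gender == "female"))
  raw$y <- as.integer((raw$cue == "high") == (raw$choice_gender == "female"))
  raw$correct <- raw$y == raw$u
  raw$congruent <- (raw$correct & raw$face_valence == "happy") |
    (!raw$correct & raw$face_valence == "sad")
  raw
}
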