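#' Decision-change table and the SN_d statistic
#'
#' For every consecutive trial pair `(k, k + 1)` a decision change means the
#' contingency-coded choice flipped (`y(k+1) != y(k)`). Pairs are binned by
#' trial `k`'s correctness, emotional congruency, and irreducible-uncertainty
#' label, giving four decision-change ratios per uncertainty condition:
#' `dc_wc` (wrong choice, congruent feedback), `dc_wi` (wrong, incongruent),
#' `dc_cc` (correct, congruent), `dc_ci` (correct, incongruent). The social
#' noise interaction statistic is
#' `SN_d = (dc_wc - dc_wi) - (dc_cc - dc_ci)`: positive when incongruent
#' (noisy) feedback damps the belief update, making wrong-choice agents
#' repeat and correct-choice agents switch. Empty cells give `NA` ratios and
#' an `NA` SN_d rather than fabricated zeros; counts are always reported.
#'
#' @param data A per-trial tibble with columns `y`, `correct`, `congruent`,
#'   `uncertainty_label` (and `cue` when `cue_matched = TRUE`); at least 2
#'   trials.
#' @param cue_matched If `TRUE`, pair each trial with the next trial sharing
#'   the same cue instead of the immediately following trial. Default
#'   `FALSE` (consecutive pairing regardless of cue).
#' @return A tibble with one row per uncertainty condition: `condition`,
#'   cell counts `n_*` and change counts `changed_*` for
#'   `wc`/`wi`/`cc`/`ci`, the four ratios `dc_*`, and `snd`.
#' @export
decision_change_table <- function(data, cue_matched = FALSE) {
  require_columns(data, c("y", "correct", "congruent", "uncertainty_label"),
                  "data")
  n <- nrow(data)
  abort_if(n < 2, "data must contain at least 2 trials")

  if (cue_matched) {
    require_columns(data, "cue", "data")
    partner <- vapply(seq_len(n), function(k) {
      nxt <- which(data$cue[seq_len(n) > k] == data$cue[k])
      if (length(nxt) == 0) NA_integer_ else k + nxt[1]
    }, integer(1))
  } else {
    partner <- c(seq_len(n - 1) + 1L, NA_integer_)
  }
  eligible <- !is.na(partner)

  pairs <- tibble::tibble(
    changed = data$y[partner[eligible]] != data$y[eligible],
    correct = data$correct[eligible],
    congruent = data$congruent[eligible],
    condition = data$uncertainty_label[eligible]
  )
  cell_of <- function(correct, congruent) {
    paste0(ifelse(correct, "c", "w"), ifelse(congruent, "c", "i"))
  }
  pairs$cell <- cell_of(pairs$correct, pairs$congruent)

  purrr::map_dfr(c("low", "high"), function(cond) {
    sub <- pairs[pairs$condition == cond, ]
    row <- list(condition = cond)
    for (cl in c("wc", "wi", "cc", "ci")) {
      inc <- sub$cell == cl
      row[[paste0("n_", cl)]] <- sum(inc)
      row[[paste0("changed_", cl)]] <- sum(sub$changed[inc])
      row[[paste0("dc_", cl)]] <-
        if (sum(inc) == 0) NA_real_ else mean(sub$changed[inc])
    }
    row$snd <- (row$dc_wc - row$dc_wi) - (row$dc_cc - row$dc_ci)
    tibble::as_tibble(row)
  })
}

#' Group test of SN_d against zero
#'
#' Two-sided one-sample t-test of per-subject SN_d values against 0, with
#' `df = n - 1`. Undefined (`NA`) values are excluded and counted.
#'
#' @param snd_values Numeric vector of per-subject SN_d values (may contain
#'   `NA` for subjects with empty cells).
#' @return A one-row tibble: `mean_snd`, `t`, `df`, `p`, `n`, `n_excluded`.
#' @export
snd_group_test <- function(snd_values) {
  keep <- is.finite(snd_values)
  n_excluded <- sum(!keep)
  x <- snd_values[keep]
  abort_if(length(x) < 2, "need at least 2 finite SN_d values")
  if (stats::sd(x) == 0) {
    t <- if (mean(x) == 0) 0 else sign(mean(x)) * Inf
    p <- if (mean(x) == 0) 1 else 0
    return(tibble::tibble(mean_snd = mean(x), t = t, df = length(x) - 1,
                          p = p, n = length(x), n_excluded = n_excluded))
  }
  tt <- stats::t.test(x, mu = 0)
  tibble::tibble(mean_snd = mean(x), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value, n = length(x),
                 n_excluded = n_excluded)
}

#' Correlation between the social-noise parameter and SN_d
#'
#' Spearman rank correlation (average ranks for ties) between per-subject
#' `tau` estimates and SN_d values, with a two-sided p-value.
#'
#' @param tau,snd Paired numeric vectors; pairs with a non-finite member are
#'   dropped. At least 3 complete pairs required.
#' @return A one-row tibble: `rho`, `p`, `n`.
#' @export
tau_snd_correlation <- function(tau, snd) {
  abort_if(length(tau) != length(snd), "tau and snd must have equal length")
  keep <- is.finite(tau) & is.finite(snd)
  abort_if(sum(keep) < 3, "need at least 3 complete pairs")
  ct <- suppressWarnings(
    stats::cor.test(tau[keep], snd[keep], method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}
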