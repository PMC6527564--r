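#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a task schedule
#'
#' Step plot of the true cue--outcome contingency across trials, with the
#' high-irreducible-uncertainty band around chance shaded.
#'
#' @param schedule A schedule tibble from [generate_schedule()].
#' @param label_threshold Shading half-width around 0.5 (matches the
#'   labelling threshold; default 0.3).
#' @return A ggplot object.
#' @export
plot_schedule <- function(schedule, label_threshold = 0.3) {
  ggplot2::ggplot(schedule,
                  ggplot2::aes(x = .data$trial_index, y = .data$p_assoc)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = 0.5 - label_threshold, ymax = 0.5 + label_threshold,
                      alpha = 0.15) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "trial", y = "p(association)",
                  title = "Cue-outcome contingency across the task") +
    ggplot2::theme_minimal()
}

#' Plot a belief trajectory
#'
#' Facets the filtered belief by hierarchy level: the outcome-probability
#' prediction at level 1, the tendency (with a +/- 1 posterior-sd ribbon) at
#' level 2, and log-volatility at level 3.
#'
#' @param object An `hgfs_trajectory` from [filter_hgfs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hgfs_trajectory
#' @export
autoplot.hgfs_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(trial = df$trial, level = "level 1 (p prediction)",
                   mu = df$muhat1, lo = NA_real_, hi = NA_real_),
    tibble::tibble(trial = df$trial, level = "level 2 (tendency)",
                   mu = df$mu2, lo = df$mu2 - sqrt(df$sigma2),
                   hi = df$mu2 + sqrt(df$sigma2)),
    tibble::tibble(trial = df$trial, level = "level 3 (log-volatility)",
                   mu = df$mu3, lo = df$mu3 - sqrt(df$sigma3),
                   hi = df$mu3 + sqrt(df$sigma3))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$mu)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~level, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "trial", y = "belief") +
    ggplot2::theme_minimal()
}

#' Plot model-selection results
#'
#' Bar chart of expected frequencies, exceedance and protected exceedance
#' probabilities per model.
#'
#' @param object A `bms_result` from [rfx_bms()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bms_result
#' @export
autoplot.bms_result <- function(object, ...) {
  df <- tidy.bms_result(object) |>
    tidyr::pivot_longer(c("expected_frequency", "exceedance_prob",
                          "protected_exceedance_prob"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~quantity) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Random-effects Bayesian model selection") +
    ggplot2::theme_minimal()
}

#' Plot a perturbation experiment
#'
#' Per-subject paired outcomes (original vs increased social noise) for the
#' three belief-fluctuation levels and the low-uncertainty SN_d.
#'
#' @param object A `perturbation_result` from
#'   [tau_perturbation_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perturbation_result
#' @export
autoplot.perturbation_result <- function(object, ...) {
  s <- object$subjects
  long <- dplyr::bind_rows(
    tibble::tibble(subject = s$subject, outcome = "fluctuation level 1",
                   original = s$fluct1_orig, perturbed = s$fluct1_pert),
    tibble::tibble(subject = s$subject, outcome = "fluctuation level 2",
                   original = s$fluct2_orig, perturbed = s$fluct2_pert),
    tibble::tibble(subject = s$subject, outcome = "fluctuation level 3",
                   original = s$fluct3_orig, perturbed = s$fluct3_pert),
    tibble::tibble(subject = s$subject, outcome = "SN_d (low uncertainty)",
                   original = s$snd_low_orig, perturbed = s$snd_low_pert)
  ) |>
    tidyr::pivot_longer(c("original", "perturbed"),
                        names_to = "arm", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arm, y = .data$value,
                                     group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Effect of raising social noise by %g",
                                  object$delta_tau)) +
    ggplot2::theme_minimal()
}
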