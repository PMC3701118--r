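#' Plot a response distribution with its Gaussian fit
#'
#' Observed proportions of "same" responses per step offset, the fitted
#' Gaussian (when supplied or computable), and optionally the feedback
#' probability curve the training phase drew from.
#'
#' @param object A `response_distribution`.
#' @param fit A `gaussian_fit` for the same distribution; computed with
#'   [fit_gaussian()] when `NULL`.
#' @param feedback Optional `feedback_distribution` overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.response_distribution <- function(object, fit = NULL,
                                           feedback = NULL, ...) {
  fit <- fit %||% fit_gaussian(object)
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$step_offset, y = .data$prop_same)
  ) +
    ggplot2::geom_col(fill = "grey70", width = 0.8)
  if (!is.null(feedback)) {
    p <- p + ggplot2::geom_line(
      data = feedback,
      ggplot2::aes(x = .data$step_offset, y = .data$p_same),
      linetype = "dashed", colour = "grey35"
    )
  }
  if (isTRUE(fit$converged)) {
    grid <- tibble::tibble(step_offset = seq(-8, 8, by = 0.1))
    grid$fitted <- fit$alpha *
      exp(-0.5 * ((fit$mu - grid$step_offset) / fit$sigma)^2)
    p <- p + ggplot2::geom_line(
      data = grid,
      ggplot2::aes(x = .data$step_offset, y = .data$fitted),
      colour = "black"
    )
  }
  p +
    ggplot2::labs(
      x = "step offset from 16 Hz (half-JND steps)",
      y = "proportion 'same' responses",
      title = sprintf(
        "Phase %s response distribution", attr(object, "phase") %||% "?"
      )
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1.05)) +
    ggplot2::theme_minimal()
}

#' Plot a Gaussian fit
#'
#' @param object A `gaussian_fit`.
#' @param ... Unused.
#' @return A ggplot object showing observed and fitted bin values.
#' @export
autoplot.gaussian_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$data, c("observed", "fitted"),
    names_to = "series", values_to = "p_same"
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$step_offset, y = .data$p_same,
      colour = .data$series, linetype = .data$series
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$series == "observed", ]) +
    ggplot2::scale_colour_manual(
      values = c(observed = "grey30", fitted = "black")
    ) +
    ggplot2::labs(
      x = "step offset (half-JND steps)", y = "proportion 'same'"
    ) +
    ggplot2::theme_minimal()
}

#' Staircase diagram of an acuity phase
#'
#' Frequency difference against trial number for both interleaved tracks of
#' one acuity test, with reversals (the averaged peaks and valleys) marked.
#'
#' @param trials A trial-log tibble.
#' @param phase Acuity phase to plot (1 or 5).
#' @param finger `"trained"` or `"untrained"`.
#' @return A ggplot object.
#' @export
plot_staircase <- function(trials, phase = 1, finger = "trained") {
  sub <- trials[
    trials$phase == phase & trials$finger == finger &
      !is.na(trials$track_side),
  ]
  if (nrow(sub) == 0L) {
    stop("no acuity trials for phase ", phase, ", finger ", finger, ".",
      call. = FALSE
    )
  }
  sub <- sub |>
    dplyr::group_by(.data$track_side) |>
    dplyr::mutate(track_trial = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(
    sub,
    ggplot2::aes(x = .data$track_trial, y = .data$diff_hz)
  ) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = sub[sub$reversal, ],
      colour = "black", shape = 21, fill = "white", size = 2
    ) +
    ggplot2::facet_wrap(~track_side, ncol = 1) +
    ggplot2::labs(
      x = "trial within track", y = "frequency difference (Hz)",
      title = sprintf("Phase %s staircases (%s finger)", phase, finger)
    ) +
    ggplot2::theme_minimal()
}

#' Cohort-level normalized JND change
#'
#' Per-subject normalized JND changes by condition, with the group median
#' marked.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @return A ggplot object.
#' @export
plot_jnd_change <- function(cohort) {
  ggplot2::ggplot(
    cohort,
    ggplot2::aes(x = .data$condition, y = .data$normalized_jnd_change)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(
      fun = median, geom = "crossbar", width = 0.4, linewidth = 0.4
    ) +
    ggplot2::labs(
      x = NULL, y = "normalized JND change (Phase 5 vs Phase 1)"
    ) +
    ggplot2::theme_minimal()
}
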