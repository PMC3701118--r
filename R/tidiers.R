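#' Tidy a Gaussian response-distribution fit
#'
#' @param x A `gaussian_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`alpha`, `mu`, `sigma`,
#'   `sigma_hz`).
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "mu", "sigma", "sigma_hz"),
    estimate = c(x$alpha, x$mu, x$sigma, x$sigma_hz)
  )
}

#' One-row summary of a Gaussian fit
#'
#' @inheritParams tidy.gaussian_fit
#' @return A one-row tibble with the parameters, goodness of fit and
#'   convergence flag.
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, mu = x$mu, sigma = x$sigma, sigma_hz = x$sigma_hz,
    goodness_r = x$goodness_r, converged = x$converged,
    n_bins = nrow(x$data)
  )
}

#' One-row summary of a simulated session
#'
#' Flattens a `tact_experiment` into the per-subject row used by cohort
#' tables: JNDs and normalized change (trained and, for Experiment 2,
#' untrained finger), Phase 2/4 fitted breadths in steps and Hz, fit
#' goodness, points, and the observer's baseline and final adaptable state.
#'
#' @param x A `tact_experiment`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.tact_experiment <- function(x, ...) {
  out <- tibble::tibble(
    subject_id = x$subject_id,
    condition = x$condition,
    experiment = x$experiment,
    seed = x$seed,
    sigma_sensory_hz = unname(x$observer$sigma_sensory_hz[["trained"]]),
    criterion0_hz = x$observer$criterion_hz,
    jnd1_hz = x$jnd_phase1$pooled_hz,
    jnd5_hz = x$jnd_phase5$pooled_hz,
    jnd1_above_hz = x$jnd_phase1$above16_hz,
    jnd1_below_hz = x$jnd_phase1$below16_hz,
    normalized_jnd_change = x$normalized_jnd_change,
    sigma2_steps = x$fit2$sigma,
    sigma4_steps = x$fit4$sigma,
    sigma2_hz = x$fit2$sigma_hz,
    sigma4_hz = x$fit4$sigma_hz,
    delta_sigma_steps = x$fit4$sigma - x$fit2$sigma,
    delta_sigma_hz = x$fit4$sigma_hz - x$fit2$sigma_hz,
    goodness_r2 = x$fit2$goodness_r,
    goodness_r4 = x$fit4$goodness_r,
    total_points = x$total_points,
    sigma_readout_final_hz = x$final_state$sigma_readout_hz,
    criterion_final_hz = x$final_state$criterion_hz
  )
  if (!is.null(x$normalized_jnd_change_untrained)) {
    out$jnd1_untrained_hz <- x$jnd_phase1_untrained$pooled_hz
    out$jnd5_untrained_hz <- x$jnd_phase5_untrained$pooled_hz
    out$normalized_jnd_change_untrained <- x$normalized_jnd_change_untrained
  }
  out
}

#' Tidy cohort statistics
#'
#' @param x A `cohort_stats` object.
#' @param ... Unused.
#' @return A tibble with one row per test (`test`, `statistic`/`estimate`,
#'   `p.value`, `n`).
#' @export
tidy.cohort_stats <- function(x, ...) {
  row <- function(test, st) {
    tibble::tibble(
      test = test,
      statistic = st$statistic %||% NA_real_,
      estimate = st$estimate %||% NA_real_,
      p.value = st$p.value,
      n = st$n
    )
  }
  out <- dplyr::bind_rows(
    row("jnd_phase1_vs_phase5_signed_rank", x$jnd_change),
    row("sigma_phase2_vs_phase4_signed_rank", x$breadth_change),
    row("cor_delta_sigma_vs_jnd_change", x$breadth_vs_jnd_change),
    row("cor_baseline_sigma_vs_jnd", x$baseline_breadth_vs_jnd)
  )
  if (!is.null(x$baseline_between_groups)) {
    out <- dplyr::bind_rows(
      out, row("baseline_jnd_between_groups_rank_sum", x$baseline_between_groups)
    )
  }
  out
}

#' One-row summary of cohort statistics
#'
#' @inheritParams tidy.cohort_stats
#' @return A one-row tibble with the headline quantities.
#' @export
glance.cohort_stats <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    median_normalized_jnd_change = x$median_normalized_jnd_change,
    p_jnd_change = x$jnd_change$p.value,
    p_breadth_change = x$breadth_change$p.value,
    r_breadth_vs_jnd_change = x$breadth_vs_jnd_change$estimate,
    r_baseline = x$baseline_breadth_vs_jnd$estimate
  )
}
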