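#' Response distribution of a category phase
#'
#' Aggregates a trial log into the proportion of "same" responses at each of
#' the 17 step offsets for one feedback-free category phase (2 or 4; Phase 3
#' is also accepted for diagnostics). Step sizes in Hz are recovered from
#' the logged stimulus frequencies so that fitted breadths can be converted
#' between step and Hz units.
#'
#' @param trials A trial-log tibble (from [run_experiment()] or
#'   [read_trial_log()]).
#' @param phase Which phase to aggregate (2 or 4; 3 allowed).
#' @return A tibble of class `response_distribution` with columns
#'   `step_offset`, `n_trials`, `prop_same`, and attributes `phase`,
#'   `step_above_hz`, `step_below_hz`, `mean_step_hz`.
#' @export
build_response_distribution <- function(trials, phase) {
  stopifnot(length(phase) == 1L, phase %in% c(2L, 3L, 4L))
  sub <- trials[trials$phase == phase & !is.na(trials$step_offset), ]
  if (nrow(sub) == 0L) {
    stop("trial log contains no phase ", phase, " category trials.",
      call. = FALSE
    )
  }
  out <- sub |>
    dplyr::group_by(step_offset = .data$step_offset) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      prop_same = mean(.data$response == "same"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$step_offset)

  ref <- sub$f1_hz[1]
  up <- sub$step_offset > 0
  dn <- sub$step_offset < 0
  step_above <- if (any(up)) {
    mean((sub$f2_hz[up] - ref) / sub$step_offset[up])
  } else {
    NA_real_
  }
  step_below <- if (any(dn)) {
    mean((sub$f2_hz[dn] - ref) / sub$step_offset[dn])
  } else {
    NA_real_
  }
  attr(out, "phase") <- as.integer(phase)
  attr(out, "step_above_hz") <- step_above
  attr(out, "step_below_hz") <- step_below
  attr(out, "mean_step_hz") <- mean(c(step_above, step_below), na.rm = TRUE)
  class(out) <- c("response_distribution", class(out))
  out
}

#' Fit a Gaussian to a response distribution
#'
#' Least-squares fit of `P(same) = alpha * exp(-0.5 * ((mu - d) / sigma)^2)`
#' to the 17 (offset, proportion) points, by Levenberg-Marquardt.
#' Initialization: `alpha` at the maximum observed proportion, `mu = 0`,
#' `sigma = 2` steps; bounds `alpha` in (0, 1.1], `mu` in \[-8, 8\],
#' `sigma` in (0.1, 16]. Goodness of fit `r` is the Pearson correlation
#' between observed and fitted proportions. A flat distribution or an
#' optimizer failure yields an honest non-converged fit with `NA`
#' parameters, never a silent bad fit.
#'
#' @param dist A `response_distribution` (or any data frame with
#'   `step_offset` and `prop_same` columns).
#' @return An object of class `gaussian_fit`: `alpha`, `mu`, `sigma` (half-
#'   JND steps), `sigma_hz` (via the mean of the above/below step sizes),
#'   `goodness_r`, `converged`, and the underlying data with fitted values.
#' @export
fit_gaussian <- function(dist) {
  d <- dist$step_offset
  y <- dist$prop_same
  stopifnot(is.numeric(d), is.numeric(y), length(d) == length(y))
  mean_step <- attr(dist, "mean_step_hz") %||% NA_real_

  bad_fit <- function(reason) {
    structure(
      list(
        alpha = NA_real_, mu = NA_real_, sigma = NA_real_,
        sigma_hz = NA_real_, goodness_r = NA_real_, converged = FALSE,
        reason = reason, mean_step_hz = mean_step,
        data = tibble::tibble(step_offset = d, observed = y, fitted = NA_real_)
      ),
      class = "gaussian_fit"
    )
  }
  if (length(d) < 5L) {
    return(bad_fit("fewer than 5 bins"))
  }
  if (max(y) - min(y) < 1e-10) {
    return(bad_fit("flat response distribution"))
  }

  model <- function(p) p[1] * exp(-0.5 * ((p[2] - d) / p[3])^2)
  start <- c(alpha = min(max(max(y), 0.05), 1.1), mu = 0, sigma = 2)
  # Levenberg-Marquardt on the raw residuals (handles zero-residual data,
  # which the nls model wrapper does not)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      fn = function(p) y - model(p),
      lower = c(1e-8, -8, 0.1),
      upper = c(1.1, 8, 16),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-12, ptol = 1e-12, maxiter = 500
      )
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(bad_fit(conditionMessage(fit)))
  }
  if (!fit$info %in% 1:4) {
    return(bad_fit(fit$message))
  }
  cf <- fit$par
  yhat <- model(cf)
  r <- suppressWarnings(cor(y, yhat))
  structure(
    list(
      alpha = unname(cf["alpha"]),
      mu = unname(cf["mu"]),
      sigma = unname(cf["sigma"]),
      sigma_hz = unname(cf["sigma"]) * mean_step,
      goodness_r = r,
      converged = TRUE,
      reason = NULL,
      mean_step_hz = mean_step,
      data = tibble::tibble(step_offset = d, observed = y, fitted = yhat)
    ),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<gaussian_fit> not converged:", x$reason %||% "unknown", "\n")
  } else {
    cat(sprintf(
      "<gaussian_fit> alpha %.3f, mu %.3f, sigma %.3f steps (%.3f Hz), r %.3f\n",
      x$alpha, x$mu, x$sigma, x$sigma_hz, x$goodness_r
    ))
  }
  invisible(x)
}

#' Normalized JND change
#'
#' The headline acuity-change measure:
#' `(jnd_phase5 - jnd_phase1) / jnd_phase1`, where each phase's JND is the
#' pooled average of the above- and below-16 values. Positive values mean
#' acuity was lost (the JND widened).
#'
#' @param jnd_phase1_hz,jnd_phase5_hz Pooled JNDs in Hz (vectorized);
#'   `jnd_phase1_hz` must be positive.
#' @return Numeric change(s).
#' @export
normalized_jnd_change <- function(jnd_phase1_hz, jnd_phase5_hz) {
  if (any(!is.finite(jnd_phase1_hz)) || any(jnd_phase1_hz <= 0)) {
    stop("`jnd_phase1_hz` must be positive and finite.", call. = FALSE)
  }
  (jnd_phase5_hz - jnd_phase1_hz) / jnd_phase1_hz
}

#' Group-level statistics on a simulated cohort
#'
#' The nonparametric battery applied to a cohort table from
#' [simulate_cohort()]: Wilcoxon signed-rank tests on Phase 1 vs Phase 5
#' JNDs and on Phase 2 vs Phase 4 fitted breadths (exact when the sample is
#' small and untied, normal approximation with continuity/tie correction
#' otherwise); Pearson correlation between the breadth change (Hz) and the
#' normalized JND change (the within-subject covariance analysis); Pearson
#' correlation between Phase 2 breadth (Hz) and the Phase 1 JND (the
#' baseline consistency analysis); and, when the table mixes both feedback
#' conditions, a Wilcoxon rank-sum test on baseline JNDs across groups.
#' Identical paired samples are reported with p = 1.
#'
#' @param cohort A cohort tibble (per-subject rows) with columns
#'   `jnd1_hz`, `jnd5_hz`, `sigma2_steps`, `sigma4_steps`, `sigma2_hz`,
#'   `delta_sigma_hz`, `normalized_jnd_change`, `condition`.
#' @return An object of class `cohort_stats`; use [tidy()] for a table of
#'   tests.
#' @export
cohort_statistics <- function(cohort) {
  if (nrow(cohort) < 2L) {
    stop("cohort statistics need at least 2 subjects.", call. = FALSE)
  }
  paired_signed_rank <- function(x, y) {
    keep <- complete.cases(x, y)
    x <- x[keep]
    y <- y[keep]
    if (length(x) < 2L) {
      return(list(statistic = NA_real_, p.value = NA_real_, n = length(x)))
    }
    if (all(y - x == 0)) {
      return(list(statistic = 0, p.value = 1, n = length(x)))
    }
    w <- suppressWarnings(wilcox.test(y, x, paired = TRUE))
    list(statistic = unname(w$statistic), p.value = w$p.value, n = length(x))
  }
  pearson <- function(x, y) {
    keep <- complete.cases(x, y)
    if (sum(keep) < 3L || sd(x[keep]) == 0 || sd(y[keep]) == 0) {
      return(list(estimate = NA_real_, p.value = NA_real_, n = sum(keep)))
    }
    ct <- cor.test(x[keep], y[keep], method = "pearson")
    list(
      estimate = unname(ct$estimate), p.value = ct$p.value, n = sum(keep)
    )
  }

  out <- list(
    n_subjects = nrow(cohort),
    jnd_change = paired_signed_rank(cohort$jnd1_hz, cohort$jnd5_hz),
    breadth_change = paired_signed_rank(
      cohort$sigma2_steps, cohort$sigma4_steps
    ),
    breadth_vs_jnd_change = pearson(
      cohort$delta_sigma_hz, cohort$normalized_jnd_change
    ),
    baseline_breadth_vs_jnd = pearson(cohort$sigma2_hz, cohort$jnd1_hz),
    median_normalized_jnd_change = median(
      cohort$normalized_jnd_change,
      na.rm = TRUE
    )
  )
  if (length(unique(cohort$condition)) == 2L) {
    w <- suppressWarnings(
      wilcox.test(jnd1_hz ~ condition, data = cohort)
    )
    out$baseline_between_groups <- list(
      statistic = unname(w$statistic), p.value = w$p.value,
      n = nrow(cohort)
    )
  }
  structure(out, class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf("<cohort_stats> n = %d subjects\n", x$n_subjects))
  cat(sprintf(
    "  JND Phase1 vs Phase5: V = %.1f, p = %.4g; median normalized change %+.3f\n",
    x$jnd_change$statistic, x$jnd_change$p.value,
    x$median_normalized_jnd_change
  ))
  cat(sprintf(
    "  breadth Phase2 vs Phase4: V = %.1f, p = %.4g\n",
    x$breadth_change$statistic, x$breadth_change$p.value
  ))
  cat(sprintf(
    "  cor(delta sigma, JND change): r = %.3f, p = %.4g\n",
    x$breadth_vs_jnd_change$estimate, x$breadth_vs_jnd_change$p.value
  ))
  cat(sprintf(
    "  cor(baseline sigma_hz, JND): r = %.3f, p = %.4g\n",
    x$baseline_breadth_vs_jnd$estimate, x$baseline_breadth_vs_jnd$p.value
  ))
  invisible(x)
}
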