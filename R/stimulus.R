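#' Build a vibrotactile pulse train
#'
#' Constructs the deflection-onset schedule for a pulse train realizing a
#' target frequency over a nominal duration. The train carries
#' `n = round(frequency_hz * nominal_duration_s)` deflections with half a
#' period of lag at the beginning and at the end, so the span from first to
#' last deflection is exactly one period shorter than the nominal duration.
#' When `frequency_hz * nominal_duration_s` is fractional, the realized
#' period is recomputed as `1000 * nominal_duration_s / n` ms so that this
#' geometry holds exactly; the realized frequency (`1000 / period`) is
#' reported alongside the requested one.
#'
#' @param frequency_hz Target vibration frequency in Hz (positive).
#' @param nominal_duration_s Nominal train duration in seconds (positive);
#'   the product `frequency_hz * nominal_duration_s` must be at least 1.
#'
#' @return An object of class `pulse_train`: a list with the requested and
#'   realized frequency, the realized inter-deflection period (ms), the
#'   number of deflections, the ordered onset times (ms), and the fixed
#'   deflection shape parameters (2.5 ms width, 150 um amplitude).
#'
#' @examples
#' pt <- build_pulse_train(16, 1)
#' pt$n_deflections # 16
#' diff(range(pt$deflection_onsets_ms)) # 937.5 ms span
#' @export
build_pulse_train <- function(frequency_hz, nominal_duration_s = 1) {
  check_scalar_positive(frequency_hz, "frequency_hz")
  check_scalar_positive(nominal_duration_s, "nominal_duration_s")
  if (frequency_hz * nominal_duration_s < 1) {
    stop("`frequency_hz * nominal_duration_s` must be at least 1 ",
      "(the train needs one deflection).",
      call. = FALSE
    )
  }
  n <- as.integer(round_half_up(frequency_hz * nominal_duration_s))
  period_ms <- 1000 * nominal_duration_s / n
  onsets <- (seq_len(n) - 0.5) * period_ms
  structure(
    list(
      frequency_hz = frequency_hz,
      realized_frequency_hz = 1000 / period_ms,
      nominal_duration_s = nominal_duration_s,
      period_ms = period_ms,
      n_deflections = n,
      deflection_onsets_ms = onsets,
      pulse_width_ms = 2.5,
      amplitude_um = 150
    ),
    class = "pulse_train"
  )
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(
    sprintf(
      "<pulse_train> %g Hz (realized %.6g Hz), %d deflections over %g s\n",
      x$frequency_hz, x$realized_frequency_hz, x$n_deflections,
      x$nominal_duration_s
    ),
    sprintf(
      "  period %.6g ms, span %.6g ms, pulse %.1f ms / %g um\n",
      x$period_ms, diff(range(x$deflection_onsets_ms)),
      x$pulse_width_ms, x$amplitude_um
    )
  )
  invisible(x)
}

#' Render a pulse train as a sampled displacement waveform
#'
#' Optional rendering utility: places a half-sinusoidal deflection (2.5 ms,
#' 150 um peak) at every onset of a [build_pulse_train()] schedule. All
#' simulation logic consumes onset times only; the waveform exists for
#' plotting or export (e.g. `readr::write_csv()`).
#'
#' @param train A `pulse_train`.
#' @param sample_rate_hz Sampling rate of the rendered waveform (default
#'   10 kHz).
#' @return A tibble with columns `time_ms` and `displacement_um`.
#' @export
render_waveform <- function(train, sample_rate_hz = 10000) {
  stopifnot(inherits(train, "pulse_train"))
  check_scalar_positive(sample_rate_hz, "sample_rate_hz")
  dt_ms <- 1000 / sample_rate_hz
  t <- seq(0, 1000 * train$nominal_duration_s, by = dt_ms)
  y <- numeric(length(t))
  for (on in train$deflection_onsets_ms) {
    idx <- which(t >= on & t <= on + train$pulse_width_ms)
    y[idx] <- y[idx] +
      train$amplitude_um * sin(pi * (t[idx] - on) / train$pulse_width_ms)
  }
  tibble::tibble(time_ms = t, displacement_um = y)
}

#' Build the 17-frequency training stimulus set
#'
#' The training set holds 17 frequencies in one-step increments around the
#' reference: steps are half the subject's above-16 JND on the high side and
#' half the below-16 JND on the low side, covering
#' `reference - 4 * jnd_below` to `reference + 4 * jnd_above` Hz at step
#' offsets -8..+8 (offset 0 is the reference itself). The two step sizes may
#' differ, so the set is symmetric in step units but generally asymmetric in
#' Hz.
#'
#' @param jnd_above_hz,jnd_below_hz Per-side JNDs in Hz (positive);
#'   `jnd_below_hz` must be small enough that all frequencies stay positive
#'   (below 4 Hz for the 16 Hz reference).
#' @param reference_hz Reference frequency (default 16 Hz).
#'
#' @return A tibble of class `stimulus_set` with columns `step_offset`
#'   (-8..8) and `frequency_hz`, carrying `reference_hz`, `step_above_hz`
#'   and `step_below_hz` as attributes.
#'
#' @examples
#' sset <- build_stimulus_set(2, 2)
#' range(sset$frequency_hz) # 8 to 24 Hz in 1 Hz steps
#' @export
build_stimulus_set <- function(jnd_above_hz, jnd_below_hz, reference_hz = 16) {
  check_scalar_positive(jnd_above_hz, "jnd_above_hz")
  check_scalar_positive(jnd_below_hz, "jnd_below_hz")
  check_scalar_positive(reference_hz, "reference_hz")
  if (reference_hz - 4 * jnd_below_hz <= 0) {
    stop("`jnd_below_hz` of ", jnd_below_hz, " Hz would place the lowest ",
      "stimulus at or below 0 Hz (it must be < ", reference_hz / 4, " Hz).",
      call. = FALSE
    )
  }
  step_above <- jnd_above_hz / 2
  step_below <- jnd_below_hz / 2
  d <- -8:8
  freq <- reference_hz + ifelse(d >= 0, d * step_above, d * step_below)
  out <- tibble::tibble(step_offset = d, frequency_hz = freq)
  attr(out, "reference_hz") <- reference_hz
  attr(out, "step_above_hz") <- step_above
  attr(out, "step_below_hz") <- step_below
  class(out) <- c("stimulus_set", class(out))
  out
}

#' Map a frequency back to its step offset
#'
#' Inverse of [build_stimulus_set()] indexing: returns the integer step
#' offset (-8..8) of a frequency that is a member of the set, matching with
#' an absolute tolerance of 1e-9 Hz.
#'
#' @param frequency_hz Frequency (or vector of frequencies) in Hz.
#' @param set A `stimulus_set`.
#' @param tol Absolute matching tolerance in Hz.
#' @return Integer step offset(s); errors if any frequency is not in the set.
#' @export
step_offset_of <- function(frequency_hz, set, tol = 1e-9) {
  stopifnot(inherits(set, "stimulus_set"))
  vapply(frequency_hz, function(f) {
    i <- which(abs(set$frequency_hz - f) < tol)
    if (length(i) != 1L) {
      stop("frequency ", f, " Hz is not a member of the stimulus set.",
        call. = FALSE
      )
    }
    set$step_offset[i]
  }, integer(1))
}
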