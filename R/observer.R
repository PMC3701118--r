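#' Parameters of a synthetic observer
#'
#' The observer is a signal-detection model of the subjects the analysis
#' stage assumes: each stimulus frequency is perceived with additive
#' zero-mean Gaussian noise whose standard deviation combines a fixed
#' sensory component with an adaptable "readout" component,
#' `sigma_eff = sqrt(sigma_sensory^2 + sigma_readout^2)`. Same/different
#' judgments compare the perceived difference against a criterion; forced
#' choices pick the larger percept. Feedback during training can adapt the
#' readout noise (a genuine acuity change, visible to forced-choice testing)
#' and/or the criterion (a categorization-threshold change, invisible to
#' forced-choice testing), which is exactly the dissociation the paradigm is
#' designed to probe.
#'
#' A fraction `readout_shared_fraction` of the readout-noise *variance* is
#' common to both index fingers; the remainder is finger-specific and only
#' the trained finger's copy adapts. This models acuity changes living in a
#' downstream, bilaterally-driven representation (SII-like) and produces
#' partial transfer of training effects to the untrained finger.
#'
#' @param sigma_sensory_hz Fixed sensory noise s.d. in Hz; length 1 (both
#'   fingers) or a length-2 vector `c(trained =, untrained =)`.
#' @param sigma_readout_hz Initial adaptable readout noise s.d. in Hz.
#' @param readout_shared_fraction Fraction of readout-noise variance shared
#'   across fingers, in \[0, 1\].
#' @param criterion_hz Same/different criterion on the perceived frequency
#'   difference, in Hz (positive).
#' @param eta_sigma,eta_c Multiplicative learning rates for the readout
#'   noise and the criterion (nonnegative; 0 disables that pathway).
#' @param sigma_readout_floor_hz Lower bound the readout noise can never
#'   adapt below.
#'
#' @return An `observer_params` list.
#' @seealso [observer_state()], [adapt_observer()], [perceive_pair()]
#' @export
observer_params <- function(sigma_sensory_hz = 1.2,
                            sigma_readout_hz = 0.84,
                            readout_shared_fraction = 0.6,
                            criterion_hz = 2.9,
                            eta_sigma = 0.03,
                            eta_c = 0.015,
                            sigma_readout_floor_hz = 0.21) {
  if (!is.numeric(sigma_sensory_hz) ||
    !length(sigma_sensory_hz) %in% c(1L, 2L) ||
    any(!is.finite(sigma_sensory_hz)) || any(sigma_sensory_hz < 0)) {
    stop("`sigma_sensory_hz` must be 1 or 2 nonnegative finite numbers.",
      call. = FALSE
    )
  }
  if (length(sigma_sensory_hz) == 1L) {
    sigma_sensory_hz <- c(sigma_sensory_hz, sigma_sensory_hz)
  }
  names(sigma_sensory_hz) <- c("trained", "untrained")
  stopifnot(
    is.numeric(sigma_readout_hz), length(sigma_readout_hz) == 1L,
    is.finite(sigma_readout_hz), sigma_readout_hz >= 0,
    is.numeric(readout_shared_fraction),
    readout_shared_fraction >= 0, readout_shared_fraction <= 1,
    is.numeric(eta_sigma), eta_sigma >= 0,
    is.numeric(eta_c), eta_c >= 0,
    is.numeric(sigma_readout_floor_hz), sigma_readout_floor_hz >= 0
  )
  check_scalar_positive(criterion_hz, "criterion_hz")
  if (sigma_readout_hz < sigma_readout_floor_hz) {
    stop("`sigma_readout_hz` must not start below `sigma_readout_floor_hz`.",
      call. = FALSE
    )
  }
  structure(
    list(
      sigma_sensory_hz = sigma_sensory_hz,
      sigma_readout_hz = sigma_readout_hz,
      readout_shared_fraction = readout_shared_fraction,
      criterion_hz = criterion_hz,
      eta_sigma = eta_sigma,
      eta_c = eta_c,
      sigma_readout_floor_hz = sigma_readout_floor_hz
    ),
    class = "observer_params"
  )
}

#' Initialize mutable observer state
#'
#' Wraps [observer_params()] with the two quantities feedback can change
#' (current readout noise and current criterion) plus the initial readout
#' noise, which anchors the untrained finger's finger-specific residual.
#' State transitions are pure: [adapt_observer()] returns a new state.
#'
#' @param params An `observer_params` object.
#' @return An `observer_state` list.
#' @export
observer_state <- function(params = observer_params()) {
  stopifnot(inherits(params, "observer_params"))
  structure(
    list(
      params = params,
      sigma_readout_hz = params$sigma_readout_hz,
      criterion_hz = params$criterion_hz,
      sigma_readout_init_hz = params$sigma_readout_hz
    ),
    class = "observer_state"
  )
}

#' @export
print.observer_state <- function(x, ...) {
  cat(sprintf(
    "<observer_state> sigma_readout %.3f Hz, criterion %.3f Hz, sigma_eff %.3f Hz (trained)\n",
    x$sigma_readout_hz, x$criterion_hz, sigma_eff(x, "trained")
  ))
  invisible(x)
}

#' Effective perceptual noise of an observer
#'
#' For the trained finger the readout variance is the current
#' `sigma_readout^2`. For the untrained finger it mixes the shared (adapted)
#' and finger-specific (frozen at its initial value) variance components:
#' `f * sigma_readout^2 + (1 - f) * sigma_readout_init^2` with
#' `f = readout_shared_fraction`. At baseline both fingers therefore have
#' identical noise, and adaptation transfers with attenuated magnitude.
#'
#' @param state An `observer_state`.
#' @param finger `"trained"` or `"untrained"`.
#' @return Effective noise s.d. in Hz.
#' @export
sigma_eff <- function(state, finger = c("trained", "untrained")) {
  finger <- match.arg(finger)
  p <- state$params
  v_read <- if (finger == "trained") {
    state$sigma_readout_hz^2
  } else {
    p$readout_shared_fraction * state$sigma_readout_hz^2 +
      (1 - p$readout_shared_fraction) * state$sigma_readout_init_hz^2
  }
  sqrt(p$sigma_sensory_hz[[finger]]^2 + v_read)
}

#' Perceive a stimulus pair
#'
#' Returns the two perceived frequencies: the physical frequencies plus
#' independent zero-mean Gaussian noise with s.d. [sigma_eff()] for the
#' given finger. Uses the session RNG stream (seed upstream with
#' `set.seed()`).
#'
#' @inheritParams sigma_eff
#' @param f1_hz,f2_hz Physical frequencies of the two intervals in Hz.
#' @return Named numeric vector `c(p1 =, p2 =)` of perceived frequencies.
#' @export
perceive_pair <- function(f1_hz, f2_hz, state,
                          finger = c("trained", "untrained")) {
  s <- sigma_eff(state, finger)
  p <- c(f1_hz, f2_hz) + rnorm(2, 0, s)
  c(p1 = p[1], p2 = p[2])
}

#' Forced-choice decision: which interval felt higher?
#'
#' Returns `"first_higher"` iff `p1 > p2`; an exact tie is broken by a fair
#' coin. This is the response rule of the acuity test ("select the stimulus
#' with higher frequency") and, having no criterion in it, is immune to
#' criterion shifts.
#'
#' @param p1,p2 Perceived frequencies in Hz.
#' @return `"first_higher"` or `"second_higher"`.
#' @export
decide_forced_choice <- function(p1, p2) {
  if (p1 > p2) {
    "first_higher"
  } else if (p2 > p1) {
    "second_higher"
  } else if (runif(1) < 0.5) {
    "first_higher"
  } else {
    "second_higher"
  }
}

#' Same/different decision against the criterion
#'
#' `"same"` iff the absolute perceived difference does not exceed the
#' observer's current criterion.
#'
#' @inheritParams decide_forced_choice
#' @param state An `observer_state`.
#' @return `"same"` or `"different"`.
#' @export
decide_same_different <- function(p1, p2, state) {
  if (abs(p2 - p1) <= state$criterion_hz) "same" else "different"
}

#' Closed-form probability of a "same" response
#'
#' Analytic companion of [decide_same_different()]: with both percepts
#' carrying independent Gaussian noise of s.d. `sigma_eff_hz`, the perceived
#' difference is Gaussian with s.d. `sigma_eff_hz * sqrt(2)` around the true
#' difference `delta_hz`, so
#' \deqn{P(\mathrm{same}) = \Phi\!\left(\frac{c-\Delta}{\sigma\sqrt2}\right) -
#'   \Phi\!\left(\frac{-c-\Delta}{\sigma\sqrt2}\right).}
#' Used as the independent oracle against Monte-Carlo response rates.
#'
#' @param delta_hz True frequency difference(s) in Hz.
#' @param sigma_eff_hz Effective noise s.d. in Hz (positive).
#' @param criterion_hz Decision criterion in Hz (positive).
#' @return Probability (vectorized over `delta_hz`).
#' @export
p_same_closed_form <- function(delta_hz, sigma_eff_hz, criterion_hz) {
  check_scalar_positive(sigma_eff_hz, "sigma_eff_hz")
  check_scalar_positive(criterion_hz, "criterion_hz")
  s <- sigma_eff_hz * sqrt(2)
  pnorm((criterion_hz - delta_hz) / s) - pnorm((-criterion_hz - delta_hz) / s)
}

#' Feedback-driven observer adaptation
#'
#' The learning rule applied on every feedback (Phase 3) trial. Matched
#' trials leave the state unchanged. A mismatch pushes both adaptable
#' quantities multiplicatively toward the feedback: "same" feedback after a
#' "different" response widens (`* exp(eta)`), "different" feedback after a
#' "same" response sharpens (`* exp(-eta)`, readout noise clamped at its
#' floor). With `eta_sigma = 0` the observer is criterion-only; with
#' `eta_c = 0`, acuity-only.
#'
#' @param state An `observer_state`.
#' @param response,feedback `"same"` or `"different"`.
#' @return The updated `observer_state`.
#' @export
adapt_observer <- function(state, response, feedback) {
  stopifnot(
    response %in% c("same", "different"),
    feedback %in% c("same", "different")
  )
  if (response == feedback) {
    return(state)
  }
  p <- state$params
  dir <- if (feedback == "same") 1 else -1
  state$sigma_readout_hz <- max(
    p$sigma_readout_floor_hz,
    state$sigma_readout_hz * exp(dir * p$eta_sigma)
  )
  state$criterion_hz <- state$criterion_hz * exp(dir * p$eta_c)
  state
}
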