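#' Create a fresh staircase track
#'
#' One 3-down-1-up track of the acuity test, running either above or below
#' the 16 Hz reference. The comparison starts 3 Hz from the reference and
#' moves in 0.5 Hz steps: harder (smaller difference) after three
#' consecutive correct responses, easier (larger difference) after any
#' error. Differences are clamped to `[0, max_diff_hz]`.
#'
#' @param side `"above16"` or `"below16"`.
#' @param start_diff_hz Starting frequency difference (Hz).
#' @param step_hz Staircase step size (Hz).
#' @param max_diff_hz Upper clamp on the difference (Hz); keeps a guessing
#'   observer's comparisons within a plausible stimulus range.
#' @return A `staircase_track` list.
#' @export
new_staircase_track <- function(side = c("above16", "below16"),
                                start_diff_hz = 3, step_hz = 0.5,
                                max_diff_hz = 5) {
  side <- match.arg(side)
  check_scalar_positive(step_hz, "step_hz")
  check_scalar_positive(max_diff_hz, "max_diff_hz")
  stopifnot(start_diff_hz >= 0, start_diff_hz <= max_diff_hz)
  structure(
    list(
      side = side,
      current_diff_hz = start_diff_hz,
      consecutive_correct = 0L,
      reversal_diffs_hz = numeric(),
      last_move = "none",
      trials_done = 0L,
      step_hz = step_hz,
      max_diff_hz = max_diff_hz,
      reversal = FALSE
    ),
    class = "staircase_track"
  )
}

#' Draw the next staircase trial
#'
#' Builds the stimulus pair for a track's current difficulty: the comparison
#' is `reference + diff` (above track) or `reference - diff` (below track),
#' and the presentation order of reference and comparison is randomized.
#' When the difference is zero the correct answer is assigned by a fair coin
#' (so the subject's response is randomly scored correct or incorrect), per
#' the paradigm's zero-difference rule.
#'
#' @param track A `staircase_track`.
#' @param reference_hz Reference frequency (default 16 Hz).
#' @return A list with `f1_hz`, `f2_hz`, `diff_hz`, `comparison_first`, and
#'   `correct_answer` (`"first_higher"`/`"second_higher"`).
#' @export
staircase_trial <- function(track, reference_hz = 16) {
  stopifnot(inherits(track, "staircase_track"))
  d <- track$current_diff_hz
  comparison <- if (track$side == "above16") {
    reference_hz + d
  } else {
    reference_hz - d
  }
  comparison_first <- runif(1) < 0.5
  f1 <- if (comparison_first) comparison else reference_hz
  f2 <- if (comparison_first) reference_hz else comparison
  correct_answer <- if (d == 0) {
    if (runif(1) < 0.5) "first_higher" else "second_higher"
  } else if (f1 > f2) {
    "first_higher"
  } else {
    "second_higher"
  }
  list(
    f1_hz = f1, f2_hz = f2, diff_hz = d,
    comparison_first = comparison_first,
    correct_answer = correct_answer
  )
}

#' Advance a staircase track by one response
#'
#' Applies the 3-down-1-up rule and records reversals. A reversal (peak or
#' valley) is logged whenever the movement direction flips, and the value
#' recorded is the extremum difference reached before the flip. Moves are
#' clamped at 0 and at `max_diff_hz`; a clamped move still counts as a move
#' in its direction, so an error at 0 Hz after a descent registers a valley
#' at 0.
#'
#' @param track A `staircase_track`.
#' @param was_correct Logical; was the response scored correct?
#' @return The updated track; `track$reversal` flags whether this trial
#'   produced a reversal.
#' @export
update_staircase <- function(track, was_correct) {
  stopifnot(inherits(track, "staircase_track"), is.logical(was_correct))
  move <- NULL
  new_diff <- track$current_diff_hz
  if (was_correct) {
    track$consecutive_correct <- track$consecutive_correct + 1L
    if (track$consecutive_correct == 3L) {
      move <- "down"
      new_diff <- max(0, track$current_diff_hz - track$step_hz)
      track$consecutive_correct <- 0L
    }
  } else {
    move <- "up"
    new_diff <- min(track$max_diff_hz, track$current_diff_hz + track$step_hz)
    track$consecutive_correct <- 0L
  }
  track$reversal <- FALSE
  if (!is.null(move)) {
    if (track$last_move != "none" && move != track$last_move) {
      track$reversal_diffs_hz <- c(
        track$reversal_diffs_hz,
        track$current_diff_hz
      )
      track$reversal <- TRUE
    }
    track$last_move <- move
    track$current_diff_hz <- new_diff
  }
  track$trials_done <- track$trials_done + 1L
  track
}

#' Threshold from staircase reversals
#'
#' The JND estimate is the arithmetic mean of the last `n_reversals`
#' (default 12) reversal differences — the "peaks and valleys" of the
#' staircase diagram. With fewer than `n_reversals` reversals available, all
#' of them are averaged and `low_reversal_flag` is set; with none, an error
#' is raised.
#'
#' @param track A `staircase_track`.
#' @param n_reversals Number of most recent reversals to average.
#' @return A list with `jnd_hz`, `n_reversals_used`, `low_reversal_flag`.
#' @export
jnd_from_reversals <- function(track, n_reversals = 12) {
  stopifnot(inherits(track, "staircase_track"))
  r <- track$reversal_diffs_hz
  if (length(r) == 0L) {
    stop("no reversals recorded on the ", track$side,
      " track; cannot estimate a JND.",
      call. = FALSE
    )
  }
  used <- tail(r, n_reversals)
  list(
    jnd_hz = mean(used),
    n_reversals_used = length(used),
    low_reversal_flag = length(r) < n_reversals
  )
}

#' Run one full acuity test
#'
#' The Phase 1/5 measurement: `n_trials` two-interval forced-choice trials
#' split between two randomly interleaved staircases above and below the
#' reference. Interleaving draws without replacement from an exact
#' half-and-half pool, so each track receives exactly `n_trials / 2` trials.
#' The observer state is read, never mutated.
#'
#' @param state An `observer_state`.
#' @param finger `"trained"` or `"untrained"`.
#' @param reference_hz Reference frequency (Hz).
#' @param n_trials Total trial count (even; default 120).
#' @param start_diff_hz,step_hz,max_diff_hz Staircase geometry, see
#'   [new_staircase_track()].
#' @param n_reversals Reversals averaged per side for the JND.
#' @return A list with `estimate` (class `jnd_estimate`: `above16_hz`,
#'   `below16_hz`, `pooled_hz`, `n_reversals_used`, `low_reversal_flag`) and
#'   `trials`, a tibble of per-trial records.
#' @export
run_acuity_test <- function(state, finger = c("trained", "untrained"),
                            reference_hz = 16, n_trials = 120,
                            start_diff_hz = 3, step_hz = 0.5,
                            max_diff_hz = 5, n_reversals = 12) {
  finger <- match.arg(finger)
  stopifnot(n_trials >= 2, n_trials %% 2 == 0)
  sides <- sample(rep(c("above16", "below16"), each = n_trials / 2))
  tracks <- list(
    above16 = new_staircase_track("above16", start_diff_hz, step_hz, max_diff_hz),
    below16 = new_staircase_track("below16", start_diff_hz, step_hz, max_diff_hz)
  )
  s_eff <- sigma_eff(state, finger)

  diff_hz <- f1v <- f2v <- numeric(n_trials)
  comp_first <- correct <- reversal <- logical(n_trials)
  resp <- ans <- character(n_trials)
  for (i in seq_len(n_trials)) {
    side <- sides[i]
    tr <- tracks[[side]]
    trial <- staircase_trial(tr, reference_hz)
    p <- trial_percepts(trial$f1_hz, trial$f2_hz, s_eff)
    r <- decide_forced_choice(p[1], p[2])
    ok <- r == trial$correct_answer
    tr <- update_staircase(tr, ok)
    tracks[[side]] <- tr

    diff_hz[i] <- trial$diff_hz
    f1v[i] <- trial$f1_hz
    f2v[i] <- trial$f2_hz
    comp_first[i] <- trial$comparison_first
    resp[i] <- r
    ans[i] <- trial$correct_answer
    correct[i] <- ok
    reversal[i] <- tr$reversal
  }

  est_side <- function(tr) {
    if (length(tr$reversal_diffs_hz) == 0L) {
      # degenerate run (no direction flip in n_trials/2 trials): fall back
      # to the final difficulty and flag it rather than aborting a session
      list(
        jnd_hz = tr$current_diff_hz, n_reversals_used = 0L,
        low_reversal_flag = TRUE
      )
    } else {
      jnd_from_reversals(tr, n_reversals)
    }
  }
  ea <- est_side(tracks$above16)
  eb <- est_side(tracks$below16)
  estimate <- structure(
    list(
      above16_hz = ea$jnd_hz,
      below16_hz = eb$jnd_hz,
      pooled_hz = (ea$jnd_hz + eb$jnd_hz) / 2,
      n_reversals_used = c(above16 = ea$n_reversals_used, below16 = eb$n_reversals_used),
      low_reversal_flag = ea$low_reversal_flag || eb$low_reversal_flag
    ),
    class = "jnd_estimate"
  )
  trials <- tibble::tibble(
    trial = seq_len(n_trials),
    finger = finger,
    track_side = sides,
    diff_hz = diff_hz,
    f1_hz = f1v,
    f2_hz = f2v,
    comparison_first = comp_first,
    response = resp,
    correct_answer = ans,
    correct = correct,
    reversal = reversal
  )
  list(estimate = estimate, trials = trials)
}

# inner-loop percept draw without the perceive_pair wrapper overhead
trial_percepts <- function(f1, f2, s_eff) {
  c(f1, f2) + rnorm(2, 0, s_eff)
}

#' @export
print.jnd_estimate <- function(x, ...) {
  cat(sprintf(
    "<jnd_estimate> pooled %.3f Hz (above16 %.3f, below16 %.3f; reversals %d/%d%s)\n",
    x$pooled_hz, x$above16_hz, x$below16_hz,
    x$n_reversals_used[["above16"]], x$n_reversals_used[["below16"]],
    if (x$low_reversal_flag) ", low-reversal" else ""
  ))
  invisible(x)
}
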