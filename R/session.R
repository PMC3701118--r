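#' Build the trial manifest for one session
#'
#' Lays out Phases 1-5 for a subject whose per-side JNDs are known: 120
#' acuity trials in Phases 1 and 5 (adaptive, so their stimuli are decided
#' at run time), and shuffled category-phase manifests in which each of the
#' 17 step offsets appears exactly 15 times in Phases 2 and 4 and 50 times
#' in Phase 3 (255/850/255 trials). The first stimulus of every category
#' trial is the 16 Hz reference (1 s); the second lasts 2 s. In Experiment
#' 2 the acuity phases additionally carry a 120-trial untrained-finger
#' block.
#'
#' Shuffling uses the current RNG stream; seed upstream for reproducible
#' manifests.
#'
#' @param jnd_above_hz,jnd_below_hz The subject's per-side JNDs (Hz).
#' @param condition `"wide"` or `"narrow"`.
#' @param experiment `"exp1"` or `"exp2"`.
#' @param reference_hz Reference frequency (Hz).
#' @param config Configuration list, see [default_config()].
#' @return A list of class `session_plan` with the `stimulus_set` and a
#'   `manifest` tibble (`phase`, `finger`, `trial`, `step_offset`,
#'   `feedback_on`, `dur1_s`, `dur2_s`).
#' @export
build_session_plan <- function(jnd_above_hz, jnd_below_hz,
                               condition = c("wide", "narrow"),
                               experiment = c("exp1", "exp2"),
                               reference_hz = 16,
                               config = default_config()) {
  condition <- match.arg(condition)
  experiment <- match.arg(experiment)
  sset <- build_stimulus_set(jnd_above_hz, jnd_below_hz, reference_hz)
  ses <- config$session

  acuity_block <- function(phase, finger) {
    tibble::tibble(
      phase = phase, finger = finger,
      trial = seq_len(config$staircase$n_trials),
      step_offset = NA_integer_, feedback_on = FALSE,
      dur1_s = 1, dur2_s = 1
    )
  }
  category_block <- function(phase, reps, feedback_on) {
    offsets <- sample(rep(sset$step_offset, times = reps))
    tibble::tibble(
      phase = phase, finger = "trained",
      trial = seq_along(offsets),
      step_offset = offsets, feedback_on = feedback_on,
      dur1_s = 1, dur2_s = 2
    )
  }

  blocks <- list(acuity_block(1L, "trained"))
  if (experiment == "exp2") {
    blocks <- c(blocks, list(acuity_block(1L, "untrained")))
  }
  blocks <- c(blocks, list(
    category_block(2L, ses$phase2_reps, FALSE),
    category_block(3L, ses$phase3_reps, TRUE),
    category_block(4L, ses$phase4_reps, FALSE),
    acuity_block(5L, "trained")
  ))
  if (experiment == "exp2") {
    blocks <- c(blocks, list(acuity_block(5L, "untrained")))
  }

  structure(
    list(
      stimulus_set = sset,
      manifest = dplyr::bind_rows(blocks),
      condition = condition,
      experiment = experiment
    ),
    class = "session_plan"
  )
}

# One same/different category phase (2, 3 or 4). Adapts state and draws
# from the pool only when both are supplied (Phase 3).
run_category_phase <- function(state, sset, offsets, phase, reference_hz,
                               pool = NULL, schedule = NULL) {
  n <- length(offsets)
  freq_by_offset <- sset$frequency_hz[match(-8:8, sset$step_offset)]
  with_fb <- !is.null(pool)

  f2v <- pts <- srv <- crv <- numeric(n)
  resp <- character(n)
  fb <- rep(NA_character_, n)
  if (!with_fb) pts <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    d <- offsets[i]
    f2 <- freq_by_offset[d + 9L]
    s <- sigma_eff(state, "trained")
    p <- c(reference_hz, f2) + rnorm(2, 0, s)
    r <- if (abs(p[2] - p[1]) <= state$criterion_hz) "same" else "different"
    if (with_fb) {
      drawn <- draw_feedback(pool, d)
      pool <- drawn$pool
      fb[i] <- drawn$feedback
      pts[i] <- score_trial(r, drawn$feedback, schedule)
      state <- adapt_observer(state, r, drawn$feedback)
    }
    resp[i] <- r
    f2v[i] <- f2
    srv[i] <- state$sigma_readout_hz
    crv[i] <- state$criterion_hz
  }

  trials <- tibble::tibble(
    phase = phase,
    finger = "trained",
    trial = seq_len(n),
    step_offset = as.integer(offsets),
    f1_hz = reference_hz,
    f2_hz = f2v,
    dur1_s = 1,
    dur2_s = 2,
    response = resp,
    feedback = fb,
    correct = if (with_fb) resp == fb else NA,
    points = pts,
    sigma_readout_hz = srv,
    criterion_hz = crv
  )
  list(trials = trials, state = state, pool = pool)
}

# Familiarization block: forced-choice warm-up at large (2/3/4 Hz)
# differences with veridical feedback, ending once 8 of the last 10
# responses are correct (or at max_trials). Simulated for fidelity of the
# trial flow but flagged `excluded` and never analysed.
run_familiarization <- function(state, cfg, reference_hz = 16) {
  s_eff <- sigma_eff(state, "trained")
  maxn <- cfg$max_trials
  diff_hz <- f1v <- f2v <- numeric(maxn)
  side <- resp <- ans <- character(maxn)
  comp_first <- correct <- logical(maxn)
  n <- 0L
  repeat {
    n <- n + 1L
    d <- sample(cfg$diffs_hz, 1)
    sd_side <- if (runif(1) < 0.5) "above16" else "below16"
    comparison <- if (sd_side == "above16") reference_hz + d else reference_hz - d
    cf <- runif(1) < 0.5
    f1 <- if (cf) comparison else reference_hz
    f2 <- if (cf) reference_hz else comparison
    a <- if (f1 > f2) "first_higher" else "second_higher"
    p <- c(f1, f2) + rnorm(2, 0, s_eff)
    r <- decide_forced_choice(p[1], p[2])

    diff_hz[n] <- d
    side[n] <- sd_side
    f1v[n] <- f1
    f2v[n] <- f2
    comp_first[n] <- cf
    resp[n] <- r
    ans[n] <- a
    correct[n] <- r == a
    if (n >= cfg$window &&
      sum(correct[(n - cfg$window + 1L):n]) >= cfg$criterion_correct) {
      break
    }
    if (n >= maxn) break
  }
  keep <- seq_len(n)
  tibble::tibble(
    phase = 0L,
    finger = "trained",
    trial = keep,
    track_side = side[keep],
    diff_hz = diff_hz[keep],
    f1_hz = f1v[keep],
    f2_hz = f2v[keep],
    dur1_s = 1,
    dur2_s = 1,
    comparison_first = comp_first[keep],
    response = resp[keep],
    correct_answer = ans[keep],
    correct = correct[keep]
  )
}

#' Run one full simulated session
#'
#' Executes the complete paradigm for one synthetic subject: a
#' familiarization block (excluded from analysis), the Phase 1 acuity test,
#' the same/different training sequence (Phase 2 without feedback, Phase 3
#' with biased feedback, points and observer adaptation, Phase 4 without
#' feedback), and the Phase 5 acuity retest. In Experiment 2, untrained-
#' finger acuity blocks are added to Phases 1 and 5, with block order
#' counterbalanced by subject-index parity (even indices test the trained
#' finger first). The 17-frequency training set is built from the subject's
#' own Phase 1 per-side JNDs, so the feedback breadth is scaled to baseline
#' sensitivity. Observer state changes only during Phase 3.
#'
#' All randomness flows from `seed` through R's RNG, so identical inputs
#' reproduce identical trial logs.
#'
#' @param observer An `observer_params` object (the synthetic subject).
#' @param condition Feedback condition, `"wide"` or `"narrow"`.
#' @param experiment `"exp1"` (trained finger only) or `"exp2"` (adds
#'   untrained-finger acuity tests).
#' @param seed Integer seed for the session.
#' @param subject_id Integer id recorded in the log; its parity sets the
#'   Experiment 2 finger order.
#' @param config Configuration list, see [default_config()].
#' @return An object of class `tact_experiment`: trial log (`$trials`),
#'   JND estimates (`$jnd_phase1`, `$jnd_phase5`, and `_untrained` variants
#'   for exp2), response distributions and Gaussian fits for Phases 2 and 4
#'   (`$rd2`, `$rd4`, `$fit2`, `$fit4`), `$normalized_jnd_change`,
#'   `$total_points`, the stimulus set, feedback distribution and reward
#'   schedule, and the final observer state. Use [tidy()] for a one-row
#'   summary.
#' @examples
#' res <- run_experiment(observer_params(), "wide", seed = 42)
#' res$normalized_jnd_change
#' @export
run_experiment <- function(observer = observer_params(),
                           condition = c("wide", "narrow"),
                           experiment = c("exp1", "exp2"),
                           seed = 1L,
                           subject_id = 1L,
                           config = default_config()) {
  condition <- match.arg(condition)
  experiment <- match.arg(experiment)
  stopifnot(inherits(observer, "observer_params"))
  set.seed(seed)
  state <- observer_state(observer)
  ref <- config$session$reference_hz
  sc <- config$staircase

  acuity <- function(fg) {
    run_acuity_test(
      state, fg, ref, sc$n_trials, sc$start_diff_hz, sc$step_hz,
      sc$max_diff_hz, sc$n_reversals
    )
  }
  acuity_fingers <- if (experiment == "exp2") {
    if (subject_id %% 2 == 0) c("trained", "untrained") else c("untrained", "trained")
  } else {
    "trained"
  }

  fam <- run_familiarization(state, config$familiarization, ref)

  phase1 <- lapply(setNames(acuity_fingers, acuity_fingers), acuity)
  jnd1 <- phase1$trained$estimate

  plan <- build_session_plan(
    jnd1$above16_hz, jnd1$below16_hz, condition, experiment, ref, config
  )
  sset <- plan$stimulus_set
  sigma_steps <- switch(condition,
    wide = config$feedback$sigma_steps_wide,
    narrow = config$feedback$sigma_steps_narrow
  )
  dist <- feedback_distribution(condition, sigma_steps)
  pool <- build_feedback_pool(dist, config$feedback$trials_per_stimulus)
  schedule <- reward_schedule(dist, config$feedback$penalty)

  offsets_for <- function(ph) {
    plan$manifest$step_offset[plan$manifest$phase == ph]
  }
  ph2 <- run_category_phase(state, sset, offsets_for(2L), 2L, ref)
  ph3 <- run_category_phase(
    state, sset, offsets_for(3L), 3L, ref, pool, schedule
  )
  state <- ph3$state
  ph4 <- run_category_phase(state, sset, offsets_for(4L), 4L, ref)

  phase5 <- lapply(setNames(acuity_fingers, acuity_fingers), acuity)
  jnd5 <- phase5$trained$estimate

  acuity_log <- function(res, phase) {
    df <- res$trials
    df$phase <- phase
    df$dur1_s <- 1
    df$dur2_s <- 1
    df
  }
  logs <- c(
    list(fam),
    lapply(acuity_fingers, function(fg) acuity_log(phase1[[fg]], 1L)),
    list(ph2$trials, ph3$trials, ph4$trials),
    lapply(acuity_fingers, function(fg) acuity_log(phase5[[fg]], 5L))
  )
  trials <- dplyr::bind_rows(logs)
  # acuity/familiarization rows carry the state snapshot of their epoch
  pre <- observer_state(observer)
  trials$sigma_readout_hz[is.na(trials$sigma_readout_hz)] <-
    ifelse(trials$phase[is.na(trials$sigma_readout_hz)] <= 2L,
      pre$sigma_readout_hz, state$sigma_readout_hz
    )
  trials$criterion_hz[is.na(trials$criterion_hz)] <-
    ifelse(trials$phase[is.na(trials$criterion_hz)] <= 2L,
      pre$criterion_hz, state$criterion_hz
    )
  trials$excluded <- trials$phase == 0L
  trials$cumulative_points <- cumsum(ifelse(is.na(trials$points), 0, trials$points))
  trials <- dplyr::mutate(
    trials,
    subject_id = as.integer(subject_id),
    condition = condition,
    experiment = experiment,
    .before = 1
  )
  trials <- trials[, trial_log_columns()]

  rd2 <- build_response_distribution(trials, 2L)
  rd4 <- build_response_distribution(trials, 4L)
  fit2 <- fit_gaussian(rd2)
  fit4 <- fit_gaussian(rd4)

  res <- list(
    subject_id = as.integer(subject_id),
    condition = condition,
    experiment = experiment,
    seed = seed,
    observer = observer,
    final_state = state,
    jnd_phase1 = jnd1,
    jnd_phase5 = jnd5,
    stimulus_set = sset,
    feedback = dist,
    schedule = schedule,
    rd2 = rd2,
    rd4 = rd4,
    fit2 = fit2,
    fit4 = fit4,
    normalized_jnd_change = normalized_jnd_change(
      jnd1$pooled_hz, jnd5$pooled_hz
    ),
    total_points = sum(trials$points[trials$phase == 3L]),
    trials = trials
  )
  if (experiment == "exp2") {
    res$jnd_phase1_untrained <- phase1$untrained$estimate
    res$jnd_phase5_untrained <- phase5$untrained$estimate
    res$normalized_jnd_change_untrained <- normalized_jnd_change(
      res$jnd_phase1_untrained$pooled_hz, res$jnd_phase5_untrained$pooled_hz
    )
  }
  structure(res, class = "tact_experiment")
}

trial_log_columns <- function() {
  c(
    "subject_id", "condition", "experiment", "phase", "finger", "trial",
    "excluded", "track_side", "diff_hz", "step_offset", "f1_hz", "f2_hz",
    "dur1_s", "dur2_s", "comparison_first", "response", "correct_answer",
    "correct", "feedback", "points", "cumulative_points",
    "sigma_readout_hz", "criterion_hz", "reversal"
  )
}

#' @export
print.tact_experiment <- function(x, ...) {
  cat(sprintf(
    "<tact_experiment> subject %d, %s feedback, %s (seed %d)\n",
    x$subject_id, x$condition, x$experiment, x$seed
  ))
  cat(sprintf(
    "  JND: %.3f Hz (Phase 1) -> %.3f Hz (Phase 5); normalized change %+.3f\n",
    x$jnd_phase1$pooled_hz, x$jnd_phase5$pooled_hz, x$normalized_jnd_change
  ))
  cat(sprintf(
    "  response breadth sigma: %.2f -> %.2f steps; total points %d\n",
    x$fit2$sigma, x$fit4$sigma, x$total_points
  ))
  if (!is.null(x$normalized_jnd_change_untrained)) {
    cat(sprintf(
      "  untrained finger: %.3f -> %.3f Hz; normalized change %+.3f\n",
      x$jnd_phase1_untrained$pooled_hz, x$jnd_phase5_untrained$pooled_hz,
      x$normalized_jnd_change_untrained
    ))
  }
  invisible(x)
}
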