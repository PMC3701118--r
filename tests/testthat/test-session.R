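test_that("session plans carry the full phase structure", {
  set.seed(1)
  plan <- build_session_plan(2, 1.6, "wide", "exp1")
  m <- plan$manifest
  counts <- table(m$phase)
  expect_equal(as.integer(counts[as.character(1:5)]), c(120L, 255L, 850L, 255L, 120L))
  for (ph in c(2L, 3L, 4L)) {
    tab <- table(m$step_offset[m$phase == ph])
    expect_equal(length(tab), 17L)
    expect_true(all(tab == if (ph == 3L) 50L else 15L))
  }
  expect_true(all(m$feedback_on[m$phase == 3L]))
  expect_false(any(m$feedback_on[m$phase != 3L]))
  # training trials pair a 1 s first and 2 s second stimulus
  expect_true(all(m$dur1_s[m$phase %in% 2:4] == 1))
  expect_true(all(m$dur2_s[m$phase %in% 2:4] == 2))
  expect_true(all(m$dur2_s[m$phase %in% c(1, 5)] == 1))

  # exp2 adds untrained-finger acuity blocks at both ends
  set.seed(1)
  plan2 <- build_session_plan(2, 1.6, "wide", "exp2")
  m2 <- plan2$manifest
  expect_equal(sum(m2$phase == 1 & m2$finger == "untrained"), 120L)
  expect_equal(sum(m2$phase == 5 & m2$finger == "untrained"), 120L)

  # identical seeds give identical shuffled manifests
  set.seed(99)
  a <- build_session_plan(2, 2, "narrow")$manifest
  set.seed(99)
  b <- build_session_plan(2, 2, "narrow")$manifest
  expect_identical(a, b)
})

test_that("sessions are deterministic and adapt only in Phase 3", {
  obs <- observer_params()
  r1 <- run_experiment(obs, "wide", seed = 31)
  r2 <- run_experiment(obs, "wide", seed = 31)
  expect_identical(r1$trials, r2$trials)

  tr <- r1$trials
  # state snapshots are constant everywhere except Phase 3
  for (ph in c(0, 1, 2)) {
    expect_equal(
      unique(tr$sigma_readout_hz[tr$phase == ph]), obs$sigma_readout_hz
    )
    expect_equal(unique(tr$criterion_hz[tr$phase == ph]), obs$criterion_hz)
  }
  final_sr <- tr$sigma_readout_hz[tr$phase == 3][850]
  for (ph in c(4, 5)) {
    expect_equal(unique(tr$sigma_readout_hz[tr$phase == ph]), final_sr)
  }
  # feedback and points only in Phase 3
  expect_true(all(is.na(tr$feedback[tr$phase != 3])))
  expect_true(all(!is.na(tr$feedback[tr$phase == 3])))
  expect_true(all(is.na(tr$points[tr$phase != 3])))

  # Phase 2-4 first stimulus is always the 16 Hz reference
  expect_true(all(tr$f1_hz[tr$phase %in% 2:4] == 16))

  # familiarization is present, flagged, and excluded from analysis counts
  expect_true(all(tr$excluded[tr$phase == 0]))
  expect_false(any(tr$excluded[tr$phase != 0]))
  expect_equal(
    as.integer(table(tr$phase[!tr$excluded])[as.character(1:5)]),
    c(120L, 255L, 850L, 255L, 120L)
  )
})

test_that("a non-learning observer keeps its JND across the session", {
  obs <- observer_params(eta_sigma = 0, eta_c = 0)
  for (seed in c(5, 17)) {
    res <- run_experiment(obs, "wide", seed = seed)
    # no state movement at all
    expect_equal(res$final_state$sigma_readout_hz, obs$sigma_readout_hz)
    expect_equal(res$final_state$criterion_hz, obs$criterion_hz)
    # Phase 5 equals Phase 1 up to staircase measurement noise
    expect_lt(abs(res$jnd_phase5$pooled_hz - res$jnd_phase1$pooled_hz), 1)
  }
})

test_that("points bookkeeping is consistent", {
  res <- run_experiment(observer_params(), "wide", seed = 8)
  tr <- res$trials
  p3 <- tr$points[tr$phase == 3]
  expect_true(all(p3 %in% c(7, 10, -9)))
  expect_equal(sum(p3), res$total_points)
  expect_equal(
    tr$cumulative_points,
    cumsum(ifelse(is.na(tr$points), 0, tr$points))
  )
  # every offset's pool is fully delivered: 850 feedback labels, with the
  # "same" count at each offset equal to the initial pool
  fb <- tr[tr$phase == 3, ]
  expect_equal(nrow(fb), 850L)
  pool <- build_feedback_pool(feedback_distribution("wide"))
  delivered <- tapply(fb$feedback == "same", fb$step_offset, sum)
  expect_equal(
    as.integer(delivered[as.character(-8:8)]),
    as.integer(pool$n_same)
  )
})

test_that("exp2 tests the untrained finger with counterbalanced order", {
  res_even <- run_experiment(observer_params(), "wide", "exp2",
    seed = 12, subject_id = 2
  )
  res_odd <- run_experiment(observer_params(), "wide", "exp2",
    seed = 13, subject_id = 1
  )
  for (res in list(res_even, res_odd)) {
    tr <- res$trials
    expect_equal(sum(tr$phase == 1 & tr$finger == "untrained"), 120L)
    expect_equal(sum(tr$phase == 5 & tr$finger == "untrained"), 120L)
    expect_false(is.null(res$normalized_jnd_change_untrained))
  }
  first_finger <- function(res) {
    tr <- res$trials
    tr$finger[tr$phase == 1][1]
  }
  expect_equal(first_finger(res_even), "trained")
  expect_equal(first_finger(res_odd), "untrained")
})

test_that("trial logs round-trip losslessly through CSV", {
  res <- run_experiment(observer_params(), "narrow", seed = 77)
  path <- tempfile(fileext = ".csv")
  write_trial_log(res$trials, path)
  back <- read_trial_log(path)
  expect_equal(as.data.frame(back), as.data.frame(res$trials))

  # empty log: header-only file, read back as zero rows
  empty <- res$trials[0, ]
  write_trial_log(empty, path)
  expect_equal(nrow(read_trial_log(path)), 0L)

  # malformed rows are reported with their line
  lines <- readr::read_lines(write_trial_log(res$trials, path))
  lines[5] <- sub("^[0-9]+", "oops", lines[5])
  readr::write_lines(lines, path)
  expect_error(read_trial_log(path), "line")
  unlink(path)
})

test_that("cohorts reduce to single sessions and span realistic baselines", {
  obs <- observer_params()
  co1 <- simulate_cohort(1, "wide",
    observer = obs, base_seed = 41,
    draw_baseline = FALSE
  )
  direct <- tidy(run_experiment(obs, "wide", seed = 42, subject_id = 1))
  expect_equal(as.data.frame(co1), as.data.frame(direct))

  co <- simulate_cohort(8, "wide", base_seed = 60)
  expect_equal(nrow(co), 8L)
  expect_true(all(co$jnd1_hz > 0.3 & co$jnd1_hz < 4))
  # per-subject baseline parameters actually vary
  expect_gt(sd(co$sigma_sensory_hz), 0)
})

test_that("Wide training transfers partially to the untrained finger", {
  co <- simulate_cohort(8, "wide", "exp2", base_seed = 77)
  expect_gt(median(co$normalized_jnd_change_untrained), 0)

  # the attenuation is mechanistic: after Wide training the untrained
  # finger's effective noise has grown, but less than the trained finger's
  res <- run_experiment(observer_params(), "wide", "exp2", seed = 123)
  baseline <- sigma_eff(observer_state(res$observer), "trained")
  expect_gt(sigma_eff(res$final_state, "untrained"), baseline)
  expect_lt(
    sigma_eff(res$final_state, "untrained"),
    sigma_eff(res$final_state, "trained")
  )
})

test_that("config files round-trip and merge over defaults", {
  cfg <- default_config()
  path <- tempfile(fileext = ".yaml")
  write_session_config(cfg, path)
  back <- read_session_config(path)
  expect_equal(back$staircase, cfg$staircase)
  expect_equal(back$cohort, cfg$cohort, tolerance = 1e-6)

  # a partial file only overrides what it names
  writeLines(c("staircase:", "  max_diff_hz: 4"), path)
  merged <- read_session_config(path)
  expect_equal(merged$staircase$max_diff_hz, 4)
  expect_equal(merged$staircase$step_hz, 0.5)
  expect_equal(merged$feedback, cfg$feedback)
  unlink(path)
})

test_that("session results export as JSON", {
  res <- run_experiment(observer_params(), "wide", seed = 21)
  path <- tempfile(fileext = ".json")
  write_results(res, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$reward_schedule$points_correct_same, 7)
  expect_equal(length(j$feedback_p_same), 17)
  expect_equal(j$summary[[1]]$condition, "wide")
  unlink(path)
})
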