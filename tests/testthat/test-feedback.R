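test_that("feedback probabilities follow the Gaussian profile in steps", {
  expect_equal(feedback_probability(0, 4), 1)
  expect_equal(feedback_probability(0, 1), 1)
  # Wide at twice the JND (4 steps): exp(-1/2)
  expect_equal(feedback_probability(4, 4), exp(-0.5))
  expect_equal(feedback_probability(4, 4), 0.6065, tolerance = 1e-4)
  # Wide at four times the JND: exp(-2)
  expect_equal(feedback_probability(8, 4), exp(-2))
  expect_error(feedback_probability(0, -1), "positive")
  expect_error(feedback_probability(9, 4), "-8..8")

  dist <- feedback_distribution("wide")
  expect_equal(nrow(dist), 17L)
  expect_equal(dist$p_same[dist$step_offset == 0], 1)
  # symmetric and strictly decreasing in |d|
  expect_equal(dist$p_same, rev(dist$p_same))
  upper <- dist$p_same[dist$step_offset >= 0]
  expect_true(all(diff(upper) < 0))
})

test_that("feedback pools discretize to 50 labelled trials per offset", {
  wide <- build_feedback_pool(feedback_distribution("wide"))
  expect_true(all(wide$n_same + wide$n_diff == 50L))
  expect_equal(wide$n_same[wide$step_offset == 4], 30L) # round(50 * 0.6065)
  expect_equal(wide$n_diff[wide$step_offset == 4], 20L)
  expect_equal(wide$n_same[wide$step_offset == 0], 50L)

  narrow <- build_feedback_pool(feedback_distribution("narrow"))
  expect_equal(narrow$n_same[narrow$step_offset == 8], 0L)
  expect_equal(narrow$n_diff[narrow$step_offset == 8], 50L)
})

test_that("pool draws are without replacement and conserve counts", {
  pool <- build_feedback_pool(feedback_distribution("wide"))
  set.seed(9)
  drawn <- character(50)
  for (i in 1:50) {
    res <- draw_feedback(pool, 4)
    drawn[i] <- res$feedback
    pool <- res$pool
  }
  expect_equal(sum(drawn == "same"), 30L)
  expect_equal(sum(drawn == "different"), 20L)
  expect_error(draw_feedback(pool, 4), "exhausted")

  # single-label pool is deterministic
  p1 <- build_feedback_pool(feedback_distribution("narrow"), 1)
  expect_equal(draw_feedback(p1, 0)$feedback, "same")

  # identical seeds give identical sequences
  seq_draw <- function(seed) {
    pool <- build_feedback_pool(feedback_distribution("wide"))
    set.seed(seed)
    vapply(1:20, function(i) {
      res <- draw_feedback(pool, 2)
      pool <<- res$pool
      res$feedback
    }, character(1))
  }
  expect_identical(seq_draw(123), seq_draw(123))
})

test_that("reward schedules balance expected gain across answers", {
  wide <- reward_schedule(feedback_distribution("wide"))
  expect_equal(wide$points_correct_same, 7L)
  expect_equal(wide$points_correct_different, 10L)
  expect_equal(wide$penalty, -9L)

  narrow <- reward_schedule(feedback_distribution("narrow"))
  expect_equal(narrow$points_correct_same, 14L)
  expect_equal(narrow$points_correct_different, 3L)

  for (sch in list(wide, narrow)) {
    expect_equal(sch$points_correct_same + sch$points_correct_different, 17L)
    # pre-rounding, expected gain of a fixed "same" answer equals that of a
    # fixed "different" answer: (A_b/17) * 17 A_g/17 == (A_g/17) * 17 A_b/17
    gain_same <- sch$a_b / 17 * (17 * sch$a_g / (sch$a_g + sch$a_b))
    gain_diff <- sch$a_g / 17 * (17 * sch$a_b / (sch$a_g + sch$a_b))
    expect_equal(gain_same, gain_diff)
    # integer rounding perturbs each point value by at most 0.5, so the
    # rounded expected gains can differ by at most 0.5 points per trial
    rs <- sch$a_b / 17 * sch$points_correct_same
    rd <- sch$a_g / 17 * sch$points_correct_different
    expect_lte(abs(rs - rd), 0.5)
  }

  # degenerate all-"same" feedback: nothing for "same", everything for
  # "different"
  degenerate <- reward_schedule(feedback_distribution("wide", Inf))
  expect_equal(degenerate$points_correct_same, 0L)
  expect_equal(degenerate$points_correct_different, 17L)
})

test_that("trial scoring pays matches and fines mismatches", {
  wide <- reward_schedule(feedback_distribution("wide"))
  narrow <- reward_schedule(feedback_distribution("narrow"))
  expect_equal(score_trial("same", "same", wide), 7L)
  expect_equal(score_trial("different", "different", wide), 10L)
  expect_equal(score_trial("same", "same", narrow), 14L)
  expect_equal(score_trial("different", "different", narrow), 3L)
  expect_equal(score_trial("same", "different", wide), -9L)
  expect_equal(score_trial("different", "same", narrow), -9L)
  # vectorized over a trial sequence
  expect_equal(
    score_trial(
      c("same", "same", "different"),
      c("same", "different", "different"), wide
    ),
    c(7L, -9L, 10L)
  )
})
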