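# Minimal synthetic trial log for one category phase.
fake_phase_log <- function(prop_same_by_offset, phase = 2L, n_per = 15L,
                           step_hz = 1) {
  d <- -8:8
  rows <- lapply(seq_along(d), function(i) {
    n_same <- round(prop_same_by_offset[i] * n_per)
    tibble::tibble(
      phase = phase,
      step_offset = d[i],
      f1_hz = 16,
      f2_hz = 16 + d[i] * step_hz,
      response = c(rep("same", n_same), rep("different", n_per - n_same))
    )
  })
  dplyr::bind_rows(rows)
}

test_that("response distributions aggregate per-offset same proportions", {
  log_all_same <- fake_phase_log(rep(1, 17))
  rd <- build_response_distribution(log_all_same, 2)
  expect_equal(nrow(rd), 17L)
  expect_true(all(rd$prop_same == 1))
  expect_true(all(rd$n_trials == 15L))

  log_none <- fake_phase_log(rep(0, 17))
  expect_true(all(build_response_distribution(log_none, 2)$prop_same == 0))

  # noiseless observer with criterion between steps 3 and 4 gives a
  # step-function distribution
  step_fn <- as.numeric(abs(-8:8) <= 3)
  rd_step <- build_response_distribution(fake_phase_log(step_fn), 2)
  expect_equal(rd_step$prop_same, step_fn)

  # step sizes in Hz are recovered from the logged frequencies
  expect_equal(attr(rd_step, "mean_step_hz"), 1)
  expect_error(build_response_distribution(log_all_same, 4), "no phase")
})

test_that("the same/different observer reproduces the step function", {
  sset <- build_stimulus_set(2, 2) # 1 Hz steps
  st <- noiseless_observer(criterion = 3.5)
  resp <- vapply(seq_len(nrow(sset)), function(i) {
    p <- perceive_pair(16, sset$frequency_hz[i], st)
    decide_same_different(p[1], p[2], st)
  }, character(1))
  expect_equal(resp == "same", abs(sset$step_offset) <= 3)
})

test_that("Gaussian fits recover exact parameters from clean data", {
  d <- -8:8
  truth <- list(alpha = 0.9, mu = 0, sigma = 3)
  y <- truth$alpha * exp(-0.5 * ((truth$mu - d) / truth$sigma)^2)
  rd <- tibble::tibble(step_offset = d, prop_same = y)
  fit <- fit_gaussian(rd)
  expect_true(fit$converged)
  expect_equal(fit$alpha, truth$alpha, tolerance = 1e-6)
  expect_equal(fit$mu, truth$mu, tolerance = 1e-6)
  expect_equal(fit$sigma, truth$sigma, tolerance = 1e-6)
  expect_equal(fit$goodness_r, 1, tolerance = 1e-9)

  # off-centre peak
  y2 <- 0.8 * exp(-0.5 * ((2 - d) / 2)^2)
  fit2 <- fit_gaussian(tibble::tibble(step_offset = d, prop_same = y2))
  expect_equal(fit2$mu, 2, tolerance = 1e-6)

  # mirror symmetry: relabeling d -> -d negates mu, preserves sigma
  fit2m <- fit_gaussian(tibble::tibble(step_offset = -d, prop_same = y2))
  expect_equal(fit2m$mu, -fit2$mu, tolerance = 1e-6)
  expect_equal(fit2m$sigma, fit2$sigma, tolerance = 1e-6)
})

test_that("degenerate response distributions yield honest non-fits", {
  flat <- tibble::tibble(step_offset = -8:8, prop_same = rep(0.5, 17))
  fit <- fit_gaussian(flat)
  expect_false(fit$converged)
  expect_true(is.na(fit$sigma))

  tiny <- tibble::tibble(step_offset = -1:1, prop_same = c(0.2, 1, 0.2))
  expect_false(fit_gaussian(tiny)$converged)
})

test_that("Gaussian breadth is recovered under binomial sampling noise", {
  d <- -8:8
  y_true <- 0.9 * exp(-0.5 * (d / 3)^2)
  set.seed(1234)
  sigmas <- replicate(100, {
    y_obs <- rbinom(17, 15, y_true) / 15
    fit_gaussian(tibble::tibble(step_offset = d, prop_same = y_obs))$sigma
  })
  expect_lt(abs(mean(sigmas, na.rm = TRUE) - 3) / 3, 0.15)
})

test_that("normalized JND change is the relative Phase 5 - Phase 1 shift", {
  expect_equal(normalized_jnd_change(2, 2), 0)
  expect_equal(normalized_jnd_change(2, 2.8), 0.4)
  expect_equal(normalized_jnd_change(2, 1.5), -0.25)
  expect_equal(normalized_jnd_change(c(2, 4), c(2.8, 2)), c(0.4, -0.5))
  expect_error(normalized_jnd_change(0, 2), "positive")
})

# Exhaustive sign-assignment enumeration of the paired signed-rank test,
# used as an independent oracle for the small-sample p-values.
exact_signed_rank_p <- function(x, y) {
  d <- (y - x)[y - x != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  all_v <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  p_one <- if (v_obs > n * (n + 1) / 4) {
    mean(all_v >= v_obs)
  } else {
    mean(all_v <= v_obs)
  }
  min(2 * p_one, 1)
}

test_that("cohort statistics match exact enumeration and trivial cases", {
  set.seed(88)
  n <- 7
  jnd1 <- runif(n, 1, 3)
  jnd5 <- jnd1 + rnorm(n, 0.2, 0.4)
  cohort <- tibble::tibble(
    condition = "wide",
    jnd1_hz = jnd1,
    jnd5_hz = jnd5,
    sigma2_steps = runif(n, 2, 4),
    sigma4_steps = runif(n, 2, 5),
    sigma2_hz = runif(n, 1, 4),
    delta_sigma_hz = runif(n, -1, 2),
    normalized_jnd_change = (jnd5 - jnd1) / jnd1
  )
  st <- cohort_statistics(cohort)
  expect_equal(st$jnd_change$p.value, exact_signed_rank_p(jnd1, jnd5))

  # identical paired samples: no difference, p = 1
  same <- cohort
  same$jnd5_hz <- same$jnd1_hz
  expect_equal(cohort_statistics(same)$jnd_change$p.value, 1)

  # exact linear relation: Pearson r = 1
  lin <- cohort
  lin$normalized_jnd_change <- 2 * lin$delta_sigma_hz
  expect_equal(
    cohort_statistics(lin)$breadth_vs_jnd_change$estimate, 1
  )
  expect_error(cohort_statistics(cohort[1, ]), "at least 2")
})

test_that("tidiers expose fits and sessions as tidy tables", {
  d <- -8:8
  y <- 0.9 * exp(-0.5 * (d / 3)^2)
  fit <- fit_gaussian(tibble::tibble(step_offset = d, prop_same = y))
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "mu", "sigma", "sigma_hz"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_bins, 17L)

  res <- run_experiment(observer_params(), "wide", seed = 3)
  row <- tidy(res)
  expect_equal(nrow(row), 1L)
  expect_equal(row$jnd1_hz, res$jnd_phase1$pooled_hz)
  expect_equal(
    row$normalized_jnd_change,
    (row$jnd5_hz - row$jnd1_hz) / row$jnd1_hz
  )
})
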