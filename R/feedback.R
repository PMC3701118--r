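#' Probability of "same" feedback at a step offset
#'
#' The biased feedback follows a Gaussian profile in half-JND step units:
#' `p_same(d) = exp(-d^2 / (2 * sigma_steps^2))`, with `sigma_steps = 4`
#' (twice the JND) in the Wide condition and `sigma_steps = 1` (half the
#' JND) in the Narrow condition. The profile peaks at 1 for identical
#' stimuli, is symmetric in `d`, and strictly decreases in `|d|`.
#'
#' @param d Integer step offset(s), in -8..8.
#' @param sigma_steps Feedback breadth in half-JND steps (positive; `Inf`
#'   gives the degenerate all-"same" limit).
#' @return Probability of "same" feedback (vectorized over `d`).
#' @export
feedback_probability <- function(d, sigma_steps) {
  if (!is.numeric(sigma_steps) || length(sigma_steps) != 1L ||
    is.na(sigma_steps) || sigma_steps <= 0) {
    stop("`sigma_steps` must be a single positive number.", call. = FALSE)
  }
  if (any(abs(d) > 8)) {
    stop("step offsets must lie in -8..8.", call. = FALSE)
  }
  if (is.infinite(sigma_steps)) {
    return(rep(1, length(d)))
  }
  exp(-d^2 / (2 * sigma_steps^2))
}

#' Build a Wide or Narrow feedback distribution
#'
#' Tabulates [feedback_probability()] over the 17 step offsets -8..8.
#' Because offsets are half-JND steps, the distribution is symmetric in step
#' units but asymmetric in Hz whenever the subject's above- and below-16
#' JNDs differ.
#'
#' @param condition `"wide"` or `"narrow"`.
#' @param sigma_steps Override of the condition's breadth (defaults: 4 for
#'   Wide, 1 for Narrow).
#' @return A tibble of class `feedback_distribution` with columns
#'   `step_offset` and `p_same`; `condition` and `sigma_steps` attributes.
#' @export
feedback_distribution <- function(condition = c("wide", "narrow"),
                                  sigma_steps = NULL) {
  condition <- match.arg(condition)
  sigma_steps <- sigma_steps %||% switch(condition, wide = 4, narrow = 1)
  d <- -8:8
  out <- tibble::tibble(
    step_offset = d,
    p_same = feedback_probability(d, sigma_steps)
  )
  attr(out, "condition") <- condition
  attr(out, "sigma_steps") <- sigma_steps
  class(out) <- c("feedback_distribution", class(out))
  out
}

#' Discretize a feedback distribution into a finite draw pool
#'
#' Every subject receives the same feedback counts: for each offset the pool
#' holds `round(trials_per_stimulus * p_same)` "same" labels (halves rounded
#' up) and the remainder "different" labels. [draw_feedback()] then samples
#' without replacement, so after all draws the delivered counts equal the
#' pool exactly.
#'
#' @param dist A `feedback_distribution`.
#' @param trials_per_stimulus Pool size per offset (default 50).
#' @return A tibble of class `feedback_pool` with columns `step_offset`,
#'   `n_same`, `n_diff`.
#' @export
build_feedback_pool <- function(dist, trials_per_stimulus = 50) {
  stopifnot(inherits(dist, "feedback_distribution"))
  check_scalar_positive(trials_per_stimulus, "trials_per_stimulus")
  n_same <- as.integer(round_half_up(trials_per_stimulus * dist$p_same))
  out <- tibble::tibble(
    step_offset = dist$step_offset,
    n_same = n_same,
    n_diff = as.integer(trials_per_stimulus) - n_same
  )
  attr(out, "trials_per_stimulus") <- as.integer(trials_per_stimulus)
  attr(out, "condition") <- attr(dist, "condition")
  class(out) <- c("feedback_pool", class(out))
  out
}

#' Draw one feedback label without replacement
#'
#' Samples uniformly among the labels remaining at offset `d` and decrements
#' the drawn label's count. Errors when the offset's pool is exhausted.
#'
#' @param pool A `feedback_pool`.
#' @param d Integer step offset.
#' @return A list with `feedback` (`"same"`/`"different"`) and the updated
#'   `pool`.
#' @export
draw_feedback <- function(pool, d) {
  i <- match(d, pool$step_offset)
  if (is.na(i)) {
    stop("offset ", d, " is not in the feedback pool.", call. = FALSE)
  }
  ns <- pool$n_same[i]
  nd <- pool$n_diff[i]
  total <- ns + nd
  if (total == 0L) {
    stop("feedback pool exhausted at step offset ", d, ".", call. = FALSE)
  }
  if (runif(1) < ns / total) {
    pool$n_same[i] <- ns - 1L
    list(feedback = "same", pool = pool)
  } else {
    pool$n_diff[i] <- nd - 1L
    list(feedback = "different", pool = pool)
  }
}

#' Reward schedule balancing "same" and "different" answers
#'
#' Point values are inversely related to the a-priori probability of each
#' feedback label, so that the expected gain of always answering "same"
#' equals that of always answering "different". With
#' `A_b = sum(p_same(d))` over the 17 offsets (total probability mass of
#' "same" feedback) and `A_g = 17 - A_b`, a correct "same" earns
#' `round(17 * A_g / (A_g + A_b))` points and a correct "different"
#' `round(17 * A_b / (A_g + A_b))`; any mismatch costs 9 points. For the
#' standard breadths this yields 7/10 (Wide) and 14/3 (Narrow).
#'
#' @param dist A `feedback_distribution`.
#' @param penalty Points for a mismatched response (default -9).
#' @return A `reward_schedule` list with `points_correct_same`,
#'   `points_correct_different`, `penalty`, and the underlying areas `a_g`,
#'   `a_b`.
#' @export
reward_schedule <- function(dist, penalty = -9L) {
  stopifnot(inherits(dist, "feedback_distribution"))
  n_off <- nrow(dist)
  a_b <- sum(dist$p_same)
  a_g <- n_off - a_b
  total <- a_g + a_b
  structure(
    list(
      condition = attr(dist, "condition"),
      sigma_steps = attr(dist, "sigma_steps"),
      a_g = a_g,
      a_b = a_b,
      points_correct_same = as.integer(round_half_up(n_off * a_g / total)),
      points_correct_different = as.integer(round_half_up(n_off * a_b / total)),
      penalty = as.integer(penalty)
    ),
    class = "reward_schedule"
  )
}

#' @export
print.reward_schedule <- function(x, ...) {
  cat(sprintf(
    "<reward_schedule> %s (sigma %g steps): correct same %+d, correct different %+d, mismatch %+d\n",
    x$condition %||% "custom", x$sigma_steps, x$points_correct_same,
    x$points_correct_different, x$penalty
  ))
  invisible(x)
}

#' Score one training trial
#'
#' A response matching the feedback earns that answer's point value; any
#' mismatch earns the penalty.
#'
#' @param response,feedback `"same"` or `"different"` (vectorized).
#' @param schedule A `reward_schedule`.
#' @return Integer points.
#' @export
score_trial <- function(response, feedback, schedule) {
  stopifnot(inherits(schedule, "reward_schedule"))
  ifelse(
    response == feedback,
    ifelse(response == "same",
      schedule$points_correct_same,
      schedule$points_correct_different
    ),
    schedule$penalty
  )
}
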