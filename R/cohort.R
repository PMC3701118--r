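#' Simulate a cohort of subjects
#'
#' Runs [run_experiment()] for `n_subjects` synthetic subjects. Subject `i`
#' uses seed `base_seed + i` for everything, including (when
#' `draw_baseline = TRUE`) the draw of its baseline parameters from the
#' `cohort` config block: sensory noise is log-normal
#' (`meanlog`/`sdlog`, truncated at `sigma_sensory_max_hz` to emulate
#' recruiting subjects able to perform the task; defaults give baseline
#' JNDs spanning roughly 0.7-3.4 Hz with a median near 1.7 Hz), the
#' adaptable readout noise is `readout_scale` times the sensory noise with
#' its floor at `readout_floor_scale` of the start, and the criterion is
#' `criterion_scale` times the subject's baseline effective noise so that
#' all subjects call physically identical pairs "same" at a comparable
#' rate.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param condition `"wide"` or `"narrow"`.
#' @param experiment `"exp1"` or `"exp2"`.
#' @param observer Template `observer_params`; learning rates and the
#'   readout component are taken from here for every subject.
#' @param base_seed Integer; subject `i` is seeded with `base_seed + i`.
#' @param draw_baseline Draw per-subject baseline sensory noise and
#'   criterion (default) or run every subject with the template verbatim.
#' @param config Configuration list, see [default_config()].
#' @return A tibble with one row per subject (the [tidy()] summary of each
#'   `tact_experiment`).
#' @export
simulate_cohort <- function(n_subjects,
                            condition = c("wide", "narrow"),
                            experiment = c("exp1", "exp2"),
                            observer = observer_params(),
                            base_seed = 1L,
                            draw_baseline = TRUE,
                            config = default_config()) {
  stopifnot(n_subjects >= 1)
  condition <- match.arg(condition)
  experiment <- match.arg(experiment)
  rows <- purrr::map(seq_len(n_subjects), function(i) {
    s <- base_seed + i
    obs <- observer
    if (draw_baseline) {
      set.seed(s)
      cs <- config$cohort
      repeat {
        sig <- rlnorm(1, cs$sigma_sensory_meanlog, cs$sigma_sensory_sdlog)
        if (sig <= cs$sigma_sensory_max_hz) break
      }
      sr <- cs$readout_scale * sig
      obs <- observer_params(
        sigma_sensory_hz = sig,
        sigma_readout_hz = sr,
        readout_shared_fraction = observer$readout_shared_fraction,
        criterion_hz = cs$criterion_scale * sqrt(sig^2 + sr^2),
        eta_sigma = observer$eta_sigma,
        eta_c = observer$eta_c,
        sigma_readout_floor_hz = cs$readout_floor_scale * sr
      )
    }
    tidy(run_experiment(
      obs, condition, experiment,
      seed = s, subject_id = i, config = config
    ))
  })
  dplyr::bind_rows(rows)
}
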