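#' Default session configuration
#'
#' All tunable constants of the simulated paradigm, grouped into blocks.
#' `staircase`: acuity-test geometry (3 Hz start, 0.5 Hz step, 5 Hz ceiling,
#' 120 trials, last 12 reversals). `feedback`: 50 pool trials per stimulus,
#' breadths of 4 (Wide) and 1 (Narrow) half-JND steps, -9 penalty.
#' `session`: 16 Hz reference and the 15/50/15 per-offset repetitions of
#' Phases 2/3/4. `familiarization`: up to 50 forced-choice trials at 2/3/4 Hz
#' differences, stopping at 8 correct of the last 10. `cohort`: the
#' baseline spread — sensory noise is log-normal (median ~1.19 Hz, log-sd
#' 0.4, truncated at 1.9 Hz to emulate recruiting subjects able to perform
#' the task), the adaptable readout noise scales with it (0.7x, floored at
#' a quarter of its start), and the criterion is twice the baseline
#' effective noise — chosen so simulated baseline JNDs span roughly
#' 0.7-3.4 Hz with a median near 1.7 Hz, about 10% of the 16 Hz reference.
#'
#' @return A nested list of configuration blocks.
#' @seealso [read_session_config()]
#' @export
default_config <- function() {
  list(
    observer = unclass(observer_params()),
    staircase = list(
      start_diff_hz = 3,
      step_hz = 0.5,
      max_diff_hz = 5,
      n_trials = 120,
      n_reversals = 12
    ),
    feedback = list(
      trials_per_stimulus = 50,
      sigma_steps_wide = 4,
      sigma_steps_narrow = 1,
      penalty = -9
    ),
    session = list(
      reference_hz = 16,
      phase2_reps = 15,
      phase3_reps = 50,
      phase4_reps = 15
    ),
    familiarization = list(
      max_trials = 50,
      diffs_hz = c(2, 3, 4),
      criterion_correct = 8,
      window = 10
    ),
    cohort = list(
      sigma_sensory_meanlog = log(1.19),
      sigma_sensory_sdlog = 0.4,
      sigma_sensory_max_hz = 1.9,
      readout_scale = 0.7,
      readout_floor_scale = 0.25,
      criterion_scale = 2
    )
  )
}

#' Read a session configuration file
#'
#' Reads a YAML file with any subset of the [default_config()] blocks
#' (`observer`, `staircase`, `feedback`, `session`, `familiarization`,
#' `cohort`) and merges it over the defaults, so a config file only needs to
#' state what it changes.
#'
#' @param path Path to a YAML configuration file.
#' @return A full configuration list.
#' @export
read_session_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (!is.list(user)) {
    stop("config file must contain a YAML mapping of blocks.", call. = FALSE)
  }
  modifyList(default_config(), user)
}

#' Write a session configuration file
#'
#' @param config A configuration list (e.g. from [default_config()]).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_session_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Rebuild observer_params from a config's observer block.
config_observer <- function(config) {
  ob <- config$observer
  observer_params(
    sigma_sensory_hz = unlist(ob$sigma_sensory_hz),
    sigma_readout_hz = ob$sigma_readout_hz,
    readout_shared_fraction = ob$readout_shared_fraction,
    criterion_hz = ob$criterion_hz,
    eta_sigma = ob$eta_sigma,
    eta_c = ob$eta_c,
    sigma_readout_floor_hz = ob$sigma_readout_floor_hz
  )
}
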