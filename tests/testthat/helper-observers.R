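# Non-learning observer with a fixed effective noise and criterion: the
# whole noise budget sits in the sensory component so sigma_eff == sigma.
fixed_observer <- function(sigma = 1, criterion = 2) {
  observer_state(observer_params(
    sigma_sensory_hz = sigma,
    sigma_readout_hz = 0,
    sigma_readout_floor_hz = 0,
    criterion_hz = criterion,
    eta_sigma = 0,
    eta_c = 0
  ))
}

# Deterministic observer: zero noise, so forced choices are always right
# (except at zero difference, where the coin rule applies).
noiseless_observer <- function(criterion = 2) fixed_observer(0, criterion)

# P(correct) = 0.5 at every difference the staircase can present.
guessing_observer <- function() fixed_observer(1e6, 2)

# Evaluate a same/different response probability by Monte Carlo through the
# package's own decision path.
mc_p_same <- function(delta_hz, state, n = 20000) {
  hits <- 0L
  for (i in seq_len(n)) {
    p <- perceive_pair(16, 16 + delta_hz, state)
    if (decide_same_different(p[1], p[2], state) == "same") hits <- hits + 1L
  }
  hits / n
}
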