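---
title: "Simulating feedback-biased vibrotactile learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating feedback-biased vibrotactile learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactlearn)
```

## The paradigm being simulated

The package simulates a five-phase vibrotactile frequency-discrimination
experiment built around a 16 Hz reference delivered to a fingertip:

1. **Phase 1 — acuity test.** 120 two-interval forced-choice trials
   ("which interval had the higher frequency?") split between two
   randomly interleaved 3-down-1-up staircases above and below 16 Hz.
   The just noticeable difference (JND) on each side is the mean of the
   last 12 staircase reversals; the pooled JND is the average of the two
   sides.
2. **Phase 2 — baseline categorization.** 255 same/different trials: a
   1 s 16 Hz reference followed by a 2 s comparison drawn from a
   17-frequency set in half-JND steps around 16 Hz (offsets −8..+8; 15
   repetitions per offset). No feedback.
3. **Phase 3 — biased-feedback training.** 850 trials (50 per offset)
   with feedback and points. The probability of "same" feedback is
   Gaussian in step units with σ = 4 steps (**Wide**, twice the JND) or
   σ = 1 step (**Narrow**, half the JND), drawn without replacement from
   a finite pool so every subject receives identical feedback counts.
4. **Phase 4 — post-training categorization.** Identical to Phase 2.
5. **Phase 5 — acuity retest.** Identical to Phase 1.

A familiarization block (up to 50 forced-choice trials at easy 2/3/4 Hz
differences, terminating once 8 of the last 10 are correct) precedes
Phase 1; it is simulated so the trial flow is faithful, flagged
`excluded`, and never analysed. In the two-hand variant (`exp2`),
120-trial acuity blocks on the untrained finger are appended to Phases 1
and 5, their order counterbalanced by subject-index parity (even
indices test the trained finger first).

Because the stimulus steps are half the subject's *own* per-side JNDs,
the feedback breadth is scaled to each subject's baseline sensitivity,
and the step grid is symmetric in step units but asymmetric in Hz
whenever the above- and below-16 JNDs differ.

## The observer model

The synthetic subject is a signal-detection observer. A physical
frequency $f$ is perceived as $f + \varepsilon$,
$\varepsilon \sim N(0, \sigma_\mathrm{eff}^2)$, with

$$\sigma_\mathrm{eff}^2 = \sigma_\mathrm{sensory}^2 + \sigma_\mathrm{readout}^2 .$$

The split matters: $\sigma_\mathrm{sensory}$ is fixed per finger, while
$\sigma_\mathrm{readout}$ is the *adaptable* component, standing for the
resolution with which a downstream, bilaterally driven stage reads out
the topographic sensory representation. A fraction
`readout_shared_fraction` of the readout **variance** is common to both
fingers; the remainder is finger-specific and frozen at its initial
value for the untrained finger. At baseline both fingers therefore carry
identical noise, and any training-induced readout change transfers to
the untrained finger with attenuated magnitude — the signature of
learning located downstream of the strictly topographic representation.

Decisions:

- forced choice: report the interval with the larger percept (ties, a
  measure-zero event under noise, are broken by a fair coin);
- same/different: report "same" iff $|p_2 - p_1| \le c$ for criterion
  $c$. The closed form
  $P(\mathrm{same}\mid\Delta) = \Phi\!\big(\tfrac{c-\Delta}{\sigma_\mathrm{eff}\sqrt2}\big) - \Phi\!\big(\tfrac{-c-\Delta}{\sigma_\mathrm{eff}\sqrt2}\big)$
  is exposed as `p_same_closed_form()` and doubles as the independent
  oracle against which Monte-Carlo response rates are tested.

### The learning rule

The experiment's data constrain *what* adapts (acuity and/or criterion)
but not *how*; the rule below is this package's declared design choice.
On every Phase 3 trial whose response mismatches the feedback, both
adaptable quantities move multiplicatively toward the feedback:

- feedback "same", response "different" (the observer distinguished a
  pair the computer called identical):
  $\sigma_\mathrm{readout} \leftarrow \sigma_\mathrm{readout} e^{\eta_\sigma}$,
  $c \leftarrow c\, e^{\eta_c}$;
- feedback "different", response "same":
  $\sigma_\mathrm{readout} \leftarrow \max(\mathrm{floor},\ \sigma_\mathrm{readout} e^{-\eta_\sigma})$,
  $c \leftarrow c\, e^{-\eta_c}$.

Matched trials change nothing, and no state changes outside Phase 3.
Multiplicative updates keep both quantities positive without ad-hoc
clipping (only the readout floor binds), and make the equilibrium scale
with the subject's own baseline, which is appropriate for a paradigm
whose stimuli are JND-scaled. The two rates are independent precisely so
that the three theoretically interesting observers are all expressible:

- **criterion-only** ($\eta_\sigma = 0$): matches the feedback bias by
  moving its category boundary. Its Phase 2→4 response distribution
  broadens, but its forced-choice JND — which has no criterion in it —
  does not move systematically. This is the null model the acuity test
  is designed to expose.
- **acuity learner** ($\eta_\sigma > 0$): genuinely loses (Wide) or
  gains (Narrow) resolution; the JND moves with the response breadth.
- **mixed** (the default): both pathways active.

An asymmetry falls out of the architecture rather than being programmed
in: under Narrow feedback the readout noise quickly reaches its floor,
so simulated Narrow cohorts show a small, often non-significant JND
decrease while Wide cohorts show a robust increase — observers start
near their resolution ceiling, with much more room to get worse than to
get better.

## Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `sigma_sensory_hz` | 1.2 | Hz | with the readout default, baseline JND ≈ 1.7 Hz, ~10% of 16 Hz |
| `sigma_readout_hz` | 0.84 | Hz | 0.7 × sensory: adaptable share of variance ≈ 33% |
| `readout_shared_fraction` | 0.6 | — | transfer to the untrained finger is present but attenuated |
| `criterion_hz` | 2.9 | Hz | 2 × baseline σ_eff: ~84% "same" at Δ = 0, like baseline subjects |
| `eta_sigma` | 0.03 | per mismatch | 850 trials suffice to approach the feedback breadth |
| `eta_c` | 0.015 | per mismatch | criterion adapts, but does not absorb the whole mismatch |
| `sigma_readout_floor_hz` | 0.21 | Hz | 25% of the start; bounds sharpening |

Cohort baselines (block `cohort` of `default_config()`): sensory noise
is log-normal (`meanlog = log 1.19`, `sdlog = 0.4`), truncated at
1.9 Hz; readout is 0.7 × sensory; criterion is 2 × baseline σ_eff. The
resulting Phase 1 JNDs span roughly 0.7–3.4 Hz with a median near
1.7 Hz — the range a realistic adult cohort shows on this task. The
truncation emulates subject recruitment: a person whose below-16 JND
reached 4 Hz could not be given the 17-stimulus set at all (the lowest
frequency would hit 0 Hz), and such a subject would not have produced a
usable staircase in the first place. `build_stimulus_set()` still errors
on such inputs rather than silently clamping.

The learning rates and the shared fraction are *free simulation
parameters*: nothing in a behavioral data set of this design pins down
their magnitudes, only the directions and orderings of the effects they
produce. They are defaults to be varied, not estimates.

## What the synthetic cohorts do and do not emulate

The generator reproduces the statistical structure the analysis assumes:
Gaussian perceptual noise, criterion-based categorization,
feedback-driven adaptation, JND-scaled stimulus sets, finite feedback
pools, and baseline heterogeneity with the observed JND range. Passing
tests therefore show that the pipeline — staircases, fits, statistics —
recovers the properties of observers *known* to have them, and that the
dissociation logic (criterion change invisible to forced choice, acuity
change visible to both tasks) behaves as designed.

They deliberately do not emulate: attention lapses, reaction times,
fatigue or session-order effects, asymmetric adaptation above vs below
16 Hz, inter-subject differences in learning rate, or any specific human
subject's numbers. Group medians of the simulated normalized JND change
depend on the chosen rates; only their signs, orderings and
correlations are meaningful claims. One consequence worth noting: within
a single all-Wide cohort of identical learners, the *true* per-subject
changes are nearly homogeneous, so the correlation between breadth
change and JND change is dominated by measurement noise; the
within-subject covariance analysis is therefore run on cohorts pooling
the Wide and Narrow groups, which is also how the corresponding
human analysis pools its subjects.

## Numerical choices

- **Pulse trains.** `n = round(fT)` deflections at a realized period of
  `1000·T/n` ms, half a period of lag at each end, so the span is
  exactly one period shorter than nominal for fractional frequencies
  too; the realized frequency is logged beside the requested one.
- **Staircase.** Start 3 Hz, step 0.5 Hz, clamp to [0, 5] Hz. The
  ceiling (never reached by realistic observers) keeps guessing
  observers finite; the zero-difference trial scores by a fair coin,
  which guarantees reversals even for a noiseless observer. A reversal
  is recorded at each direction flip, at the extremum reached before the
  flip. Clamped moves still count as moves in their direction. Fewer
  than 12 reversals: average what exists and flag, never abort a
  session; a track with *no* reversals (possible only in pathological
  configurations) falls back to its final difficulty, flagged.
- **Interleaving** draws the two tracks' 60 + 60 trial order without
  replacement, guaranteeing exact counts.
- **Feedback pool.** `round(50·p_same)` "same" labels per offset
  (halves away from zero), remainder "different"; sampling without
  replacement. Published probability tables for this paradigm contain a
  few cells that no single Gaussian reproduces; the Gaussian form is
  taken as normative since it reproduces the published 0.60 fraction and
  all four point values exactly.
- **Reward rounding** is half-away-from-zero on each point value
  independently; the rounded values for both standard breadths sum
  to 17. Pre-rounding, the expected gains of fixed "same" and fixed
  "different" strategies are exactly equal; rounding perturbs each gain
  by at most 0.5 points per trial.
- **Gaussian fits** use Levenberg–Marquardt on the raw residuals
  (`minpack.lm::nls.lm`; the `nls` model wrapper cannot handle the
  zero-residual case). Start: α at the maximum observed proportion,
  μ = 0, σ = 2 steps; bounds α ∈ (0, 1.1], μ ∈ [−8, 8],
  σ ∈ (0.1, 16]; `ftol = ptol = 1e-12`. Flat distributions and
  optimizer failures return `converged = FALSE` with `NA` parameters.
  Goodness of fit is the Pearson correlation between observed and
  fitted bins. σ is reported in half-JND steps and converted to Hz with
  the mean of the above/below step sizes (the convention declared for
  asymmetric JNDs).
- **Rank tests** delegate to `wilcox.test`: exact for small untied
  samples, normal approximation with correction otherwise; all-zero
  paired differences are reported as p = 1 rather than an error.
- **Determinism.** Every random element of a session flows from one
  `set.seed(seed)`; subject *i* of a cohort uses `base_seed + i`, and
  its baseline draw happens inside that seed, so cohorts are exactly
  reproducible and a one-subject cohort equals the corresponding single
  run.

## Problem sizes used in the test suite

The suite exercises full sessions (1600 analysed trials each) and
cohorts of 8–18 subjects; stochastic properties use 50–200 seeded
replicates (staircase convergence and fit recovery) and 10⁴–10⁵
Monte-Carlo draws (oracle-equivalence checks), sizes at which the
Monte-Carlo standard errors are several times smaller than the
tolerances being asserted.

## Known limitations

- The learning rule is one reasonable instantiation; the data it is
  built to mirror cannot distinguish it from other monotone rules with
  the same equilibrium behavior.
- Readout-noise transfer is modelled as a variance mixture with a single
  shared fraction; richer topographies (per-frequency channels, partial
  criterion transfer) are out of scope.
- The criterion has no floor or ceiling; extreme configurations (e.g.
  enormous `eta_c` with pathological feedback) can push it far from the
  stimulus range, which is visible in the logs but not prevented.
- `simulate_cohort()` draws baseline heterogeneity only in the noise
  components and criterion; learning rates are homogeneous within a
  cohort.
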