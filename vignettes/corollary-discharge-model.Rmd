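---
title: "A two-state sensor model of corollary-discharge modulation in the lateral line"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-state sensor model of corollary-discharge modulation in the lateral line}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reafference)
library(dplyr)
```

## The problem

Swimming fish flood their own lateral line with self-generated flow
(reafference). A copy of the motor command — the corollary discharge (CD)
— reaches the hair cells through cholinergic efferents and inhibits
transmission strictly during swim bouts. The classical view is that this
inhibition *cancels* reafference. The alternative examined here is that
inhibition *restructures* it: by suppressing release, the CD protects the
synapse from adaptation and confines the surviving spikes to a narrow
phase band around the peak of each body-wave cycle, turning a noisy,
heterogeneous sensor sheet into a phase-locked peak detector — a source
of proprioceptive information about the body wave itself.

`reafference` implements the computational side of that argument: a
minimal stochastic sensor, the circular statistics used to quantify
phase-locked feedback, the inhibition-ratio analysis with its
response-type clustering, heterogeneous-population simulations, and a
synthetic-experiment generator so the full analysis pipeline can run
without any recordings.

## The two-state sensor

A sensor (a hair-cell/afferent unit) is either *sensitive* (state 1) or
*insensitive* (state 2). At each time step:

* a sensitive sensor releases — emits a spike — with probability
  `p_b = clip((k1 * s(t) + k2 * s0) * lambda_star, 0, 1)` and becomes
  insensitive;
* an insensitive sensor regenerates with probability
  `p_c = clip(k3 * lambda_star, 0, 1)`.

`s(t)` is the stimulus, `k1` its gain, `s0` the spontaneous release rate
(expected spikes per stimulus wavelength), and `k2 ∈ [0, 1]` the
inhibition constant multiplying the spontaneous term (`k2 = 1`: CD OFF).
`lambda_star = f / fs` converts per-wavelength rates into per-step
probabilities on a grid sampled at `fs` (2 kHz by default), so `fs / f`
steps span one stimulus wavelength. The insensitive state is the
model's abstraction for any depletion-like process (vesicle pool
exhaustion, receptor desensitisation); no specific biophysics is
assumed. Adaptation emerges whenever release outpaces regeneration:
`classify_sensor()` labels a parameter set *adapting* when the exact
expected spike count over the last two stimulus cycles falls below half
of the first two.

Two reference parameter sets are bundled as `sensor_presets()`:

```{r presets}
sensor_presets()
g <- sim_grid(frequency = 20, sampling_rate = 2000, n_wavelengths = 20)
classify_sensor(preset_sensor("adapting"), g)
classify_sensor(preset_sensor("nonadapting"), g)
```

The preset names follow the *simulated* behaviour: the high-gain,
slow-regeneration set (`k1 = 4, k3 = 0.04, s0 = 40`) exhausts its pool
within the first cycle, which is the published rule for adaptation (gain
greatly exceeding regeneration), although the source text attaches the
opposite label to it. The package therefore classifies empirically and
never trusts printed labels.

### Conventions that required a decision

* **Stimulus sign.** The default drive is a *signed* unit sinusoid with
  the release probability clipped at zero, not a rectified one. A
  polarized hair cell is depolarized by sense-direction deflection and
  hyperpolarized by antisense deflection, so deflection should modulate
  release around the spontaneous level with zero mean. This also makes
  the nonadapting identity `R_E = R_S` exact in the linear regime: with
  a rectified stimulus the `k1` term adds net drive and biases `R_E`
  upward by several percent at strong inhibition. A rectified trace is
  available via `make_stimulus(rectified = TRUE)`.
* **Re-equilibration.** Each simulated sweep is an active half (stimulus
  and inhibition on, `n_wavelengths` cycles) followed by an equal
  re-equilibration half with the stimulus off and release *silenced*
  (`k2 = 0`). Silencing release lets the occupancy of the sensitive
  state relax back toward 1 — that is what re-equilibration means for
  this chain. The alternative reading (inhibition released, `k2 = 1`)
  keeps a high-`s0` sensor permanently depleted at rest: it would never
  show the first-cycle burst, measurable adaptation, or a calibratable
  spontaneous ratio. That mode remains available
  (`requil = "released"`) and is exactly what the rebound-spiking
  experiment needs, because rebound is the release of accumulated
  occupancy when spontaneous drive returns.
* **Spike timing.** A spike at step `t` is stamped `(t - 1) / fs`, so it
  carries the phase of the stimulus sample that drove it. Stimulus-cycle
  indices are 1-based throughout.
* **Burn-in.** The first two sweeps of every chain are flagged and
  excluded from all summaries. Long sessions are parallelized over
  independent replicate chains (each with its own burn-in); with a fixed
  seed results are bit-reproducible.
* **Discreteness.** Because a spike occupies its step, an
  instant-regeneration sensor (`p_c = 1`) has exact rate
  `p_b / (1 + p_b)` per step, not `p_b`; the familiar Bernoulli
  intuition is recovered only as `p_b -> 0`. Tests assert the exact
  chain law and the limit.

## Calibration against the observed spontaneous ratio

Nonlinearity makes `k2` and the observed spontaneous suppression `R_S`
(spontaneous rate CD ON / CD OFF) unequal, so inhibition levels are
always expressed as *measured* `R_S` and `k2` is solved for.
`calibrate_inhibition()` computes the expected spontaneous rate exactly —
a closed-form occupancy recursion through the periodic
active/re-equilibration template (or the stationary rate for swim-bout
simulations) — and bisects on `k2`. The calibration is therefore
deterministic; Monte Carlo sessions at the returned `k2` reproduce the
target up to sampling error, which the test suite checks at three
standard errors. The same exact-propagation machinery provides
`enumerate_expected_spikes()`, the oracle against which the Monte Carlo
engine is verified on short instances, and the steady-state law
`p_b p_c / (p_b + p_c)` per step for constant stimuli.

## What the simulations show

`inhibition_sweep()` is the workhorse: for each target `R_S` it
calibrates `k2`, simulates spontaneous-only and stimulated sessions with
and without inhibition, and reports `R_S`, `R_E` (evoked ratio) and
`R_E / R_S` with delta-method standard errors.

```{r sweep}
sw <- inhibition_sweep(
  preset_sensor("adapting"), g,
  targets = c(0.1, 0.5, 0.9),
  n_sweeps = 400, n_chains = 100, seed = 42
)
sw |> select(target_rs, k2, r_s, r_e, ratio, retention_pct)
```

Three behaviours carry the argument:

* **Nonadapting identity.** For the nonadapting set the model is linear
  in `k2` over a cycle, so `R_E / R_S = 1` at every inhibition level.
* **Adapting divergence.** For the adapting set, evoked output is
  regeneration-limited: suppressing release barely changes the evoked
  count while the spontaneous rate collapses, so `R_E / R_S > 1`
  whenever `R_S < 1`. At `R_S = 0.1` — a 90% suppression of spontaneous
  activity — the sensor retains well over half of its evoked spikes.
  This is the mechanism behind the third response cluster seen in the
  data: strong inhibition measured on spontaneous rates, weak inhibition
  measured on evoked rates, with the level of adaptation as the
  moderator (the `r_s × adaptation` interaction in
  `interaction_regression()`).
* **Rebound.** An inhibition-only session with `requil = "released"`
  shows depressed spontaneous rates that recover during inhibition and a
  transient rate overshoot after release, as occupancy accumulated under
  inhibition is discharged.

## Circular statistics

Spike phase is the fraction `t / T` of the stimulus cycle, used as an
angle `theta = 2*pi*(t/T mod 1)`. `vector_strength()` is the mean
resultant length (Rayleigh vector); circular variance is `-2 log VS`;
`response_gain()` is count × VS, bounded by the count, distinguishing
one reliably phase-locked spike from many unlocked ones. Quantiles of a
circular variable need an unwrapping convention: `phase_quantiles()`
maps phases into `(center − π, center + π]` around a reference (the
cell's CD-OFF median phase, which also removes the conduction delay)
and then applies ordinary type-7 linear interpolation. This is valid
because polarized responses concentrate in the sense half-cycle; it
would be inappropriate for diffuse phase distributions. Phases are
pooled across sweeps before quantiles (per-sweep quantile averaging is
a defensible alternative; pooling was chosen and is stated here rather
than asserted as the source's choice). Zero-spike cycles are reported
missing, never zero-imputed, so summaries average over observed cycles.

## The population simulation

`simulate_population()` models a fish as `n_sensors = 30` independent
sensors with log-uniform `k1, k3 ∈ [0.04, 4]` and constant `s0 = 4`,
each calibrated per sensor to the target `R_S` (stationary context) and
simulated for one 1-s, 20-cycle bout from its resting occupancy; spike
times are pooled per fish and interspike intervals across
`n_fish = 1000` fish. Sampling choices that were genuinely open: the
bounds bracket the two reference regimes; log-uniform sampling weights
slow- and fast-regenerating sensors evenly on the log scale (uniform
sampling concentrates mass at high gain/regeneration and produces an
implausibly dense, unlocked pooled train); populations are resampled
independently per fish.

Under no inhibition the pooled train is dense and phase-diffuse — most
ISIs are shorter than one cycle. At `R_S = 0.1` the pooled spikes
concentrate near the stimulus peak at π/2 (median phase within 0.25 rad
of π/2, vector strength ≈ 0.7 in the shipped tests) and the fraction of
ISIs within 10% of an integer multiple of the period is greatest, while
`R_S = 0.5` changes that fraction only marginally — the graded
signatures of cycle-locked, sparse feedback. The absolute
integer-multiple fraction remains modest because thirty pooled sensors
still yield several spikes per cycle; with unspecified sampling ranges
this is as far as the reproduction can honestly go, and the claims
tested are the ordinal ones above.

## The synthetic experiment

`generate_dataset()` emulates the recording protocol end to end: 100
sweeps of 1 s stimulation / 2 s rest at 5, 20 or 40 Hz; per-cell swim
bouts from a Poisson onset process (0.4 bouts/s) with log-normal
durations clipped to 0.06–1 s (the observed range; the histogram's
shape is not published, so median ≈ 150 ms was chosen as typical) and a
post-bout refractory gap so the equal-duration post-swim analysis
window stays swim-free; CD switches instantaneously at bout boundaries
(graded acetylcholine decay is out of scope). Cells belong to three
response types chosen to reproduce the qualitative cluster structure —
weakly adapting/strongly inhibited, intermediate/weakly inhibited, and
strongly adapting/strongly inhibited — with mild log-normal parameter
jitter; these presets are the package's own, not fitted values. The
ground truth lands in a manifest, and the shipped tests verify that
`label_spikes()` → `activity_ratios()` → `cluster_response_types()`
recovers the planted types.

What the generator does *not* emulate: electrode noise and spike-sorting
errors, gradual inhibition decay, stimulus-amplitude variability,
boundary-layer filtering, or correlations between sensors. Passing
recovery tests therefore show the pipeline is correct and the cluster
logic is sound on data of this structure — not that real recordings
will cluster as cleanly.

## Numerical choices and problem sizes

* Bisection tolerance for calibration: `1e-10` on the achieved ratio.
* Cycle-boundary assignment adds `1e-9` of a cycle before flooring, so
  spikes generated on exact boundaries are robust to float round-off;
  epoch boundaries are half-open `[start, end)`.
* k-means uses unit-variance standardization, 50 restarts and a fixed
  seed; groups are relabeled by ascending adaptation so "group 1" is
  always the weakest-adapting. Identical-point degeneracy is an error.
* The interaction regression is ordinary least squares through the
  origin with Wald 95% intervals — a deliberate simplification of the
  original mixed-effects/GAM machinery, which is why experimental-cohort
  coefficients are context rather than targets. Swim-bout time courses
  use weighted binned means on unit-normalized time instead of adaptive
  spline smooths, for the same reason.
* Spike tables round-trip through CSV exactly: times are written with 17
  significant digits and parsed with the correctly rounded base parser.
* Shipped test and acceptance runs use 2,000 retained sweeps per
  condition (250 chains × 8), 1,000 fish × 30 sensors for the
  population, and 12,000–20,000 Monte Carlo replicates for the oracle
  checks; all statistical assertions are made at three standard errors
  of the quantity being tested.

## Known limitations

* The model is phenomenological: one insensitive state, no vesicle-pool
  size, no receptor kinetics; inhibition acts only on the spontaneous
  term, exactly as the transition matrix is written, so evoked
  suppression is entirely emergent.
* Inhibition onset/offset is instantaneous; rebound magnitude is
  therefore an upper bound on what slower acetylcholine reuptake would
  produce.
* Discrete time imposes a one-step refractory period; rates saturate at
  one spike per step, so very high `s0 × lambda_star` products are
  clipped (clipping is flagged by `transition_probs()`).
* Population sampling ranges are not published; ordinal ISI claims are
  robust to that choice, absolute fractions are not.
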