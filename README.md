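# reafference

Corollary-discharge modulation of lateral-line sensory feedback.

Swimming fish stimulate their own lateral line. A copy of the motor
command — the corollary discharge (CD) — inhibits hair-cell transmission
strictly during swim bouts. `reafference` implements a computational
account of why that inhibition is useful: rather than cancelling
self-generated feedback, it protects heterogeneous, adaptation-prone
sensors from depletion and confines their spikes to a narrow phase band
at the peak of each body-wave cycle, so the surviving feedback reports
the progression of the body wave (a proprioceptive signal). The package
is aimed at sensory neuroscientists who want to simulate, calibrate and
analyse this kind of spike data with tidyverse-style tools.

## The model

A sensor is a discrete-time two-state Markov chain — *sensitive* (1) or
*insensitive* (2) — with transition matrix

```
[ 1→1  1→2 ]   [ 1 − P_B     P_B    ]        P_B = clip((K1·s(t) + K2·s0)·λ*, 0, 1)
[ 2→1  2→2 ] = [   P_C     1 − P_C  ],       P_C = clip(K3·λ*, 0, 1)
```

where `s(t)` is a unit sinusoidal stimulus, `K1` the stimulus gain,
`s0` the spontaneous release rate per stimulus wavelength, `K2 ∈ [0, 1]`
the CD inhibition constant on the spontaneous term, `K3` the
regeneration rate, and `λ* = f/fs` the per-step normalization (2 kHz
sampling by default). A spike is the 1→2 release transition. Adaptation
emerges when gain outpaces regeneration (pool depletion).

On top of the simulator the package provides:

* exact expected-count oracles and deterministic calibration of `K2`
  against the **observed** spontaneous suppression ratio `R_S`
  (`calibrate_inhibition()`, `enumerate_expected_spikes()`);
* circular spike statistics: phase quantiles (0.1/0.5/0.9), vector
  strength `VS = |Σe^{iθ}|/n`, circular variance `−2·log VS`, spike gain
  `n·VS`, PSTHs and interspike intervals;
* the inhibition-ratio analysis: evoked/spontaneous × CD ON/OFF spike
  labeling, `R_S` and `R_E` ratios, adaptation indices, k-means
  response-type clustering and the `R_S × adaptation` interaction
  regression (`label_spikes()`, `activity_ratios()`,
  `cluster_response_types()`, `interaction_regression()`);
* swim-normalized response time courses (`swim_normalized_timecourse()`);
* heterogeneous 30-sensor population simulations with ISI-structure
  analysis (`simulate_population()`, `isi_peak_analysis()`);
* a synthetic-experiment generator emulating the full recording protocol
  (`generate_dataset()`), so everything runs without external data.

## Worked example

Calibrate an adapting sensor to three inhibition levels and measure how
inhibition transfers from spontaneous to evoked rates:

```r
library(reafference)
library(dplyr)

g <- sim_grid(frequency = 20, sampling_rate = 2000, n_wavelengths = 20)
sw <- inhibition_sweep(preset_sensor("adapting"), g,
  targets = c(0.1, 0.5, 0.9), n_sweeps = 400, n_chains = 100, seed = 42
)
sw |> select(target_rs, k2, r_s, r_e, ratio, retention_pct)
#> # A tibble: 3 × 6
#>   target_rs       k2   r_s   r_e ratio retention_pct
#>       <dbl>    <dbl> <dbl> <dbl> <dbl>         <dbl>
#> 1       0.1 0.000185 0.107 0.937  8.74          93.7
#> 2       0.5 0.00155  0.521 0.964  1.85          96.4
#> 3       0.9 0.0126   0.938 0.946  1.01          94.6
```

Reading the table: at a calibrated 90% suppression of spontaneous
activity (`r_s ≈ 0.1`), the adapting sensor still delivers ~94% of its
uninhibited evoked spikes (`retention_pct`), so the evoked-to-spontaneous
inhibition ratio `R_E/R_S` is far above 1 — evoked output is
regeneration-limited and escapes the inhibition that flattens the
spontaneous rate. A nonadapting sensor instead keeps `R_E/R_S = 1` at
every level.

The same divergence produces distinct response types in a synthetic
multi-cell experiment, recovered by the clustering analysis:

```r
ds <- generate_dataset(n_cells = 30, n_sweeps = 60, seed = 3)
ar <- activity_ratios(ds$spikes, ds$epochs,
  total_duration = ds$protocol$session_length
)
cl <- cluster_response_types(ar, k = 3, seed = 1)
tidy(cl)
#> # A tibble: 3 × 5
#>   group  size   r_s   r_e delta_inhibition
#>   <int> <int> <dbl> <dbl>            <dbl>
#> 1     1    10 0.195 0.189          0.00607
#> 2     2    10 0.101 0.721         -0.619
#> 3     3    10 0.815 0.832         -0.0170
```

Two clusters sit on the identity line (`delta_inhibition ≈ 0`,
spontaneous and evoked rates equally inhibited); the strongly adapting
cluster diverges (`r_s ≈ 0.1` but `r_e ≈ 0.7`). `autoplot(cl)` draws the
`(R_S, R_E)` scatter; `tidy()`/`glance()` methods are provided for the
cluster and regression objects.

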