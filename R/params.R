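#' Sensor model parameters
#'
#' Constructs the parameter set of the two-state (sensitive/insensitive)
#' stochastic sensor. Release from the sensitive state — a spike — occurs
#' with per-step probability `(k1 * s(t) + k2 * s0) * lambda_star` (clipped
#' to `[0, 1]`), and an insensitive sensor regenerates with probability
#' `k3 * lambda_star` per step. `lambda_star` is the per-step normalization
#' of a simulation grid (see [sim_grid()]), so `s0` and `k3` are expressed
#' per stimulus wavelength.
#'
#' @param k1 Stimulus gain (dimensionless multiplier of the stimulus value).
#' @param k3 Regeneration rate, expected regenerations per stimulus
#'   wavelength.
#' @param s0 Spontaneous spike rate, expected spikes per stimulus wavelength
#'   in the absence of inhibition.
#' @param k2 Inhibition constant in `[0, 1]` multiplying the spontaneous
#'   term; `1` means no inhibition (corollary discharge OFF), values below 1
#'   model efferent inhibition of hair-cell release.
#'
#' @return An object of class `sensor_params` (a named list).
#' @examples
#' sensor_params(k1 = 4, k3 = 0.04, s0 = 40)
#' @export
sensor_params <- function(k1, k3, s0, k2 = 1) {
  stopifnot(is.numeric(k1), is.numeric(k2), is.numeric(k3), is.numeric(s0))
  if (k1 < 0) abort("`k1` must be >= 0")
  if (k2 < 0 || k2 > 1) abort("`k2` must lie in [0, 1]")
  if (k3 <= 0) abort("`k3` must be > 0")
  if (s0 < 0) abort("`s0` must be >= 0")
  structure(list(k1 = k1, k2 = k2, k3 = k3, s0 = s0), class = "sensor_params")
}

#' @export
print.sensor_params <- function(x, ...) {
  cat(sprintf(
    "<sensor_params> k1 = %g, k2 = %g, k3 = %g, s0 = %g\n",
    x$k1, x$k2, x$k3, x$s0
  ))
  invisible(x)
}

#' Reference sensor parameter sets
#'
#' The two published constant sets used throughout the simulations, named
#' here by their *simulated* behaviour under [classify_sensor()]: the
#' high-gain, slow-regeneration set (`k1 = 4`, `k3 = 0.04`, `s0 = 40`)
#' depletes its release pool within the first stimulus cycle and is
#' adapting; the low-gain, fast-regeneration set (`k1 = 0.04`, `k3 = 4`,
#' `s0 = 4`) is nonadapting. (The source labels for these two sets are
#' inconsistent with the accompanying rule that adaptation arises when gain
#' greatly exceeds regeneration; the empirical classification is used here.)
#'
#' @return A tibble with columns `preset`, `k1`, `k3`, `s0`.
#' @seealso [sensor_params()], [classify_sensor()]
#' @examples
#' sensor_presets()
#' @export
sensor_presets <- function() {
  tibble(
    preset = c("adapting", "nonadapting"),
    k1 = c(4, 0.04),
    k3 = c(0.04, 4),
    s0 = c(40, 4)
  )
}

#' Fetch a preset as a `sensor_params` object
#'
#' @param preset `"adapting"` or `"nonadapting"` (see [sensor_presets()]).
#' @param k2 Inhibition constant, passed to [sensor_params()].
#' @return A `sensor_params` object.
#' @examples
#' preset_sensor("nonadapting")
#' @export
preset_sensor <- function(preset = c("adapting", "nonadapting"), k2 = 1) {
  preset <- match.arg(preset)
  p <- sensor_presets()
  p <- p[p$preset == preset, ]
  sensor_params(k1 = p$k1, k3 = p$k3, s0 = p$s0, k2 = k2)
}

#' Simulation grid
#'
#' Defines the discrete time base of a simulation. Transition probabilities
#' are normalized per step by `lambda_star = frequency / sampling_rate`, so
#' that a rate of `R` events per stimulus wavelength becomes `R *
#' lambda_star` per step and `sampling_rate / frequency` steps span one
#' wavelength.
#'
#' @param frequency Stimulus frequency in Hz.
#' @param sampling_rate Simulation sampling rate in Hz (default 2000).
#' @param n_wavelengths Duration of the stimulated segment in stimulus
#'   wavelengths (default 20).
#' @return An object of class `sim_grid`.
#' @examples
#' sim_grid(20)
#' @export
sim_grid <- function(frequency, sampling_rate = 2000, n_wavelengths = 20) {
  if (frequency <= 0) abort("`frequency` must be > 0")
  if (sampling_rate < 10 * frequency) {
    abort("`sampling_rate` must be at least 10 * `frequency`")
  }
  period_steps <- sampling_rate / frequency
  if (abs(period_steps - round(period_steps)) > 1e-8) {
    abort("`sampling_rate` must be an integer multiple of `frequency`")
  }
  lambda_star <- frequency / sampling_rate
  stopifnot(lambda_star > 0, lambda_star < 1)
  structure(
    list(
      frequency = frequency,
      sampling_rate = sampling_rate,
      n_wavelengths = n_wavelengths,
      lambda_star = lambda_star,
      period_steps = as.integer(round(period_steps))
    ),
    class = "sim_grid"
  )
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf(
    "<sim_grid> f = %g Hz, fs = %g Hz, lambda* = %g, %d steps/wavelength, %g wavelengths\n",
    x$frequency, x$sampling_rate, x$lambda_star, x$period_steps,
    x$n_wavelengths
  ))
  invisible(x)
}
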