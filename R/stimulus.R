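#' Sinusoidal stimulus trace
#'
#' Builds the unit-peak sinusoidal dipole stimulus sampled on a simulation
#' grid, one value per time step, with the peak of each cycle at phase
#' `pi/2`. By default the signed sinusoid is returned; negative values
#' correspond to antisense deflection and contribute zero release drive
#' after clipping in [transition_probs()]. With `rectified = TRUE` the
#' negative half-cycle is set to zero instead.
#'
#' @param grid A [sim_grid()].
#' @param rectified Logical; half-wave rectify the trace?
#' @param n_wavelengths Number of wavelengths to generate (defaults to the
#'   grid's).
#' @return An object of class `stimulus_trace`: a list with `values`,
#'   `period_steps`, `frequency`.
#' @examples
#' st <- make_stimulus(sim_grid(20))
#' length(st$values)
#' @export
make_stimulus <- function(grid, rectified = FALSE, n_wavelengths = NULL) {
  stopifnot(inherits(grid, "sim_grid"))
  n_wavelengths <- n_wavelengths %||% grid$n_wavelengths
  ps <- grid$period_steps
  n <- as.integer(round(n_wavelengths * ps))
  if (n < 1) abort("stimulus must span at least one step")
  values <- sin(2 * pi * (seq_len(n) - 1) / ps)
  if (rectified) values <- pmax(values, 0)
  stimulus_trace(values, grid)
}

#' Construct a stimulus trace from raw samples
#'
#' Low-level constructor, mainly useful for constant or custom drive
#' signals (e.g. the time-invariant stimulus used to probe the steady
#' state).
#'
#' @param values Numeric vector of stimulus samples, one per time step.
#' @param grid A [sim_grid()] supplying the period and frequency.
#' @return A `stimulus_trace`.
#' @examples
#' stimulus_trace(rep(1, 100), sim_grid(20))
#' @export
stimulus_trace <- function(values, grid) {
  stopifnot(inherits(grid, "sim_grid"), is.numeric(values))
  if (length(values) == 0) abort("empty stimulus")
  if (any(!is.finite(values))) abort("stimulus values must be finite")
  structure(
    list(
      values = as.numeric(values),
      period_steps = grid$period_steps,
      frequency = grid$frequency
    ),
    class = "stimulus_trace"
  )
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf(
    "<stimulus_trace> %d steps, %d steps/wavelength, f = %g Hz, range [%g, %g]\n",
    length(x$values), x$period_steps, x$frequency,
    min(x$values), max(x$values)
  ))
  invisible(x)
}
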