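#' Spike phases with respect to a periodic stimulus
#'
#' Maps spike times onto stimulus phase. Within a stimulus cycle of period
#' `T`, a spike at time `t` (from stimulus onset) has phase fraction
#' `(t / T) mod 1` and angle `theta = 2 * pi * fraction` in `[0, 2 * pi)`.
#' The 1-based index of the stimulus cycle containing each spike is
#' attached.
#'
#' @param spike_times Spike times in seconds.
#' @param period Stimulus period `T` in seconds.
#' @param onset Stimulus onset in seconds (default 0).
#' @return A tibble with columns `time_s`, `fraction`, `theta`,
#'   `interval_index`.
#' @examples
#' spike_phases(c(0.0125, 0.05), period = 0.05)
#' @export
spike_phases <- function(spike_times, period, onset = 0) {
  if (period <= 0) abort("`period` must be > 0")
  if (any(spike_times < onset)) abort("spikes before stimulus onset")
  rel <- (spike_times - onset) / period
  tibble(
    time_s = spike_times,
    fraction = rel %% 1,
    theta = 2 * pi * (rel %% 1),
    interval_index = as.integer(floor(rel + 1e-9)) + 1L
  )
}

#' Vector strength of a set of spike phases
#'
#' The length of the mean resultant vector of phases on the unit circle,
#' `VS = sqrt((sum cos theta)^2 + (sum sin theta)^2) / n`. `VS = 1` means
#' perfect phase locking; `VS` near 0 means phases spread uniformly.
#'
#' @param theta Spike phases in radians.
#' @return Vector strength in `[0, 1]`.
#' @examples
#' vector_strength(c(0, pi / 2))
#' @export
vector_strength <- function(theta) {
  n <- length(theta)
  if (n < 1) abort("vector strength of an empty phase set is undefined")
  sqrt(sum(cos(theta))^2 + sum(sin(theta))^2) / n
}

#' Circular variance from vector strength
#'
#' `sigma^2 = -2 * log(VS)`; reported as `Inf` at `VS = 0`.
#'
#' @param vs Vector strength in `[0, 1]`.
#' @return Circular variance.
#' @examples
#' circular_variance(1)
#' @export
circular_variance <- function(vs) {
  stopifnot(all(vs >= 0 & vs <= 1))
  ifelse(vs == 0, Inf, -2 * log(vs))
}

#' Spike gain
#'
#' The product of spike count and vector strength; bounded above by the
#' count. High gain distinguishes a single reliably phase-locked spike
#' from many spikes spread over the cycle.
#'
#' @param n Spike count(s).
#' @param vs Vector strength(s) in `[0, 1]`.
#' @return `n * vs`.
#' @examples
#' response_gain(3, 0.5)
#' @export
response_gain <- function(n, vs) {
  stopifnot(all(n >= 0), all(vs >= 0 & vs <= 1))
  n * vs
}

#' Phase quantiles around a reference median
#'
#' Linear-interpolation (type 7) quantiles of spike phases, computed after
#' unwrapping each phase to the half-open interval `(center - pi, center +
#' pi]`. Responses of polarized sensors concentrate in the sense
#' half-cycle, so unwrapping around the reference median (typically the
#' cell's CD-OFF median phase) makes the linear quantiles well defined on
#' the circle.
#'
#' @param theta Spike phases in radians.
#' @param probs Quantile probabilities (default `c(0.1, 0.5, 0.9)`; the
#'   0.1-0.9 spread is the response-interval width).
#' @param center Reference angle around which phases are unwrapped
#'   (default 0, i.e. phases are assumed pre-centered).
#' @return Named numeric vector of quantiles (radians, on the unwrapped
#'   scale around `center`).
#' @examples
#' phase_quantiles(c(-0.2, 0, 0.3), probs = 0.5)
#' @export
phase_quantiles <- function(theta, probs = c(0.1, 0.5, 0.9), center = 0) {
  if (length(theta) < 1) abort("no phases supplied")
  x <- theta - center
  x <- x - 2 * pi * ceiling((x - pi) / (2 * pi))  # (-pi, pi]
  quantile(x, probs = probs, type = 7, names = TRUE) + center
}

#' Per-stimulus-interval response summary
#'
#' Summarises evoked spikes of a labeled spike table per stimulus cycle
#' and corollary-discharge state: mean spike count per sweep, pooled-phase
#' quantiles (centered on the cell's CD-OFF median phase, which removes
#' conduction delay), vector strength, circular variance, response-interval
#' width and gain. Burn-in sweeps are excluded. Cycles without spikes are
#' reported with `n = 0` and missing phase fields rather than imputed.
#'
#' @param labeled A labeled spike table (from [simulate_session()] or
#'   [label_spikes()]) with columns `evoked`, `cd_on`, `interval_index`,
#'   `stim_time`, and optionally `burn_in`, `sweep`, `cell_id`.
#' @param frequency Stimulus frequency in Hz (defaults to the table's
#'   `frequency_hz` column).
#' @param n_intervals Number of stimulus cycles to report (default: the
#'   largest observed index).
#' @param n_sweeps Number of sweeps over which mean counts are taken
#'   (default: distinct non-burn-in sweeps in the table).
#' @return A tibble with one row per `cd_state` x `interval_index`.
#' @export
per_interval_summary <- function(labeled, frequency = NULL,
                                 n_intervals = NULL, n_sweeps = NULL) {
  labeled <- as_tibble(labeled)
  frequency <- frequency %||% unique(labeled$frequency_hz)
  if (length(frequency) != 1 || !is.numeric(frequency)) {
    abort("supply a single `frequency`")
  }
  period <- 1 / frequency
  if (!"burn_in" %in% names(labeled)) labeled$burn_in <- FALSE
  ev <- filter(labeled, .data$evoked, !.data$burn_in, !is.na(.data$interval_index))
  if (is.null(n_sweeps)) {
    if ("sweep" %in% names(labeled)) {
      keys <- labeled[!labeled$burn_in, intersect(c("chain", "sweep"), names(labeled))]
      n_sweeps <- max(nrow(unique(keys)), 1L)
    } else {
      n_sweeps <- 1L
    }
  }
  n_intervals <- n_intervals %||% max(ev$interval_index, 1L)
  ev$theta <- 2 * pi * ((ev$stim_time / period) %% 1)
  off <- ev$theta[!ev$cd_on]
  center <- if (length(off) > 0) {
    2 * pi * (median((ev$stim_time[!ev$cd_on] / period) %% 1))
  } else {
    pi / 2
  }
  grid_tbl <- tidyr::expand_grid(
    cd_state = intersect(c("off", "on"), unique(ifelse(ev$cd_on, "on", "off"))),
    interval_index = seq_len(n_intervals)
  )
  ev$cd_state <- ifelse(ev$cd_on, "on", "off")
  summarise_cell <- function(th, n_spk) {
    if (n_spk == 0) {
      return(tibble(
        n = 0L, n_mean = 0, q10 = NA_real_, q50 = NA_real_, q90 = NA_real_,
        width = NA_real_, vs = NA_real_, circ_var = NA_real_, gain = NA_real_
      ))
    }
    q <- phase_quantiles(th, center = center)
    vs <- vector_strength(th)
    nm <- n_spk / n_sweeps
    tibble(
      n = n_spk, n_mean = nm,
      q10 = q[[1]] - center, q50 = q[[2]] - center, q90 = q[[3]] - center,
      width = q[[3]] - q[[1]],
      vs = vs, circ_var = circular_variance(vs),
      gain = response_gain(nm, vs)
    )
  }
  per <- ev |>
    group_by(.data$cd_state, .data$interval_index) |>
    summarise(res = list(summarise_cell(.data$theta, dplyr::n())), .groups = "drop") |>
    tidyr::unnest("res")
  out <- left_join(grid_tbl, per, by = c("cd_state", "interval_index"))
  out$n[is.na(out$n)] <- 0L
  out$n_mean[is.na(out$n_mean)] <- 0
  out$frequency_hz <- frequency
  out$center <- center
  arrange(out, .data$cd_state, .data$interval_index)
}

#' Peristimulus time histogram
#'
#' Cross-sweep mean spike rate in fixed-width bins aligned to sweep start.
#' Bins partition `[0, t_max]` exactly (the final bin may be shorter), so
#' `sum(rate * width) * n_sweeps` returns the total spike count.
#'
#' @param times Spike times in seconds from sweep start (pooled across
#'   sweeps), or a `sensor_session` (non-burn-in spikes are used and
#'   `n_sweeps`/`t_max` are filled in).
#' @param bin_width Bin width in seconds (default 0.05).
#' @param n_sweeps Number of sweeps pooled.
#' @param t_max Sweep duration in seconds.
#' @return A tibble with columns `bin`, `t_start`, `t_mid`, `width`, `n`,
#'   `rate` (spikes/s per sweep).
#' @export
psth <- function(times, bin_width = 0.05, n_sweeps = 1, t_max = NULL) {
  if (bin_width <= 0) abort("`bin_width` must be > 0")
  if (inherits(times, "sensor_session")) {
    ses <- times
    grid <- attr(ses, "grid")
    keep <- !ses$burn_in
    n_active <- round(grid$n_wavelengths * grid$period_steps)
    times <- ses$time_s[keep]  # within-sweep times span both halves
    n_sweeps <- attr(ses, "n_chains") * (attr(ses, "n_sweeps") - attr(ses, "burn_in"))
    t_max <- 2 * n_active / grid$sampling_rate
  }
  t_max <- t_max %||% max(times, bin_width)
  edges <- seq(0, t_max, by = bin_width)
  if (t_max - edges[length(edges)] > 1e-9 * t_max) edges <- c(edges, t_max)
  bins <- findInterval(times, edges, rightmost.closed = TRUE)
  bins[bins == length(edges)] <- length(edges) - 1L
  counts <- tabulate(bins, nbins = length(edges) - 1L)
  width <- diff(edges)
  tibble(
    bin = seq_along(counts),
    t_start = edges[-length(edges)],
    t_mid = edges[-length(edges)] + width / 2,
    width = width,
    n = counts,
    rate = counts / (n_sweeps * width)
  )
}

#' Interspike intervals
#'
#' Time differences between sequential spikes of a sorted spike train.
#'
#' @param spike_times Sorted spike times in seconds.
#' @return Numeric vector of length `length(spike_times) - 1` (empty for
#'   fewer than two spikes), all positive.
#' @examples
#' isi(c(0, 0.010, 0.025))
#' @export
isi <- function(spike_times) {
  if (is.unsorted(spike_times)) abort("spike times must be sorted")
  if (length(spike_times) < 2) {
    return(numeric(0))
  }
  diff(spike_times)
}
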