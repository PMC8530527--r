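#' Stimulation protocol epochs
#'
#' The recording protocol: `n_sweeps` repetitions of 1 s of sinusoidal
#' dipole stimulation followed by 2 s off, tiling the session without
#' overlap. At 20 Hz each 1-s on-epoch contains 20 stimulus cycles.
#'
#' @param frequency Stimulus frequency in Hz (5, 20 and 40 Hz were used
#'   experimentally; other values are allowed).
#' @param n_sweeps Number of on/off repetitions (default 100).
#' @param on_duration,off_duration Epoch durations in seconds.
#' @return A list of class `protocol` with `epochs` (tibble: `kind`,
#'   `sweep`, `start_s`, `end_s`), `frequency`, `n_sweeps`,
#'   `session_length`, `intervals_per_epoch`.
#' @examples
#' generate_protocol(20, n_sweeps = 3)
#' @export
generate_protocol <- function(frequency = 20, n_sweeps = 100,
                              on_duration = 1, off_duration = 2) {
  stopifnot(frequency > 0, n_sweeps >= 1, on_duration > 0, off_duration >= 0)
  sweep_len <- on_duration + off_duration
  starts <- (seq_len(n_sweeps) - 1) * sweep_len
  epochs <- tibble(
    kind = "stimulus",
    sweep = seq_len(n_sweeps),
    start_s = starts,
    end_s = starts + on_duration
  )
  structure(
    list(
      epochs = epochs,
      frequency = frequency,
      n_sweeps = n_sweeps,
      on_duration = on_duration,
      off_duration = off_duration,
      session_length = n_sweeps * sweep_len,
      intervals_per_epoch = frequency * on_duration
    ),
    class = "protocol"
  )
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf(
    "<protocol> %g Hz, %d sweeps of %g s on / %g s off (%g s total)\n",
    x$frequency, x$n_sweeps, x$on_duration, x$off_duration, x$session_length
  ))
  invisible(x)
}

#' Generate spontaneous swim bouts
#'
#' Swim-bout onsets follow a homogeneous Poisson process; durations are
#' log-normal, clipped to the observed range of larval zebrafish bouts
#' (60 ms to 1 s). Bouts never overlap: after each bout a refractory gap
#' at least as long as the bout itself is enforced, which also keeps the
#' equal-duration post-swim analysis window free of swimming.
#'
#' @param session_length Session duration in seconds.
#' @param rate Poisson onset rate (bouts per second of non-refractory
#'   time).
#' @param meanlog,sdlog Log-normal duration parameters (defaults give a
#'   median near 150 ms).
#' @param bounds Duration clip bounds in seconds.
#' @param seed Optional integer seed.
#' @return A tibble of swim epochs: `kind = "swim"`, `start_s`, `end_s`.
#' @export
generate_swim_bouts <- function(session_length, rate = 0.25,
                                meanlog = log(0.15), sdlog = 0.5,
                                bounds = c(0.06, 1), seed = NULL) {
  stopifnot(session_length > 0, rate >= 0)
  if (rate == 0) {
    return(tibble(kind = character(), start_s = numeric(), end_s = numeric()))
  }
  draw <- function() {
    starts <- numeric(0)
    ends <- numeric(0)
    t <- 0
    repeat {
      t <- t + rexp(1, rate)
      dur <- min(max(rlnorm(1, meanlog, sdlog), bounds[1]), bounds[2])
      if (t + dur >= session_length) break
      starts <- c(starts, t)
      ends <- c(ends, t + dur)
      t <- t + 2 * dur # bout + post-swim refractory gap
    }
    tibble(kind = "swim", start_s = starts, end_s = ends)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Response-type presets generating the three observed clusters:
# group 1: weakly adapting, strong inhibition (low R_S = R_E);
# group 2: intermediate adaptation, weak inhibition (high R_S = R_E);
# group 3: strongly adapting, strong inhibition (low R_S, high R_E).
.group_presets <- function() {
  tibble(
    group = 1:3,
    k1 = c(0.04, 0.4, 4),
    k3 = c(4, 1, 0.4),
    s0 = c(4, 4, 40),
    target_rs = c(0.2, 0.85, 0.2)
  )
}

#' Generate a synthetic multi-cell recording session
#'
#' Composes the two-state sensor model with the stimulation protocol and
#' per-cell swim bouts to emulate a full recording experiment. Each cell
#' is assigned one of three response types (see the cluster analysis in
#' [cluster_response_types()]), its inhibition constant is calibrated to
#' the type's target spontaneous suppression, and the corollary discharge
#' is applied instantaneously during that cell's swim bouts. Cells receive
#' mild log-normal jitter on `k1` and `k3` so the population is
#' heterogeneous within types. The ground truth (types, parameters, seeds)
#' is returned in a manifest for recovery tests.
#'
#' @param n_cells Number of cells (default 30).
#' @param mixture Proportions of the three response types (summing to 1).
#' @param frequency Stimulus frequency in Hz.
#' @param n_sweeps Protocol sweeps (default 100; scale down for quick
#'   runs).
#' @param sampling_rate Simulation rate in Hz (default 2000).
#' @param swim_rate Swim-bout onset rate per second.
#' @param jitter_sd Standard deviation of the log-normal jitter on `k1`,
#'   `k3` (0 disables).
#' @param seed Integer seed.
#' @return A list of class `synthetic_dataset`: `spikes` (labeled spike
#'   table), `epochs` (stimulus and swim epochs, `cell_id` resolved),
#'   `protocol`, and `manifest` (list with `cells` tibble and generator
#'   settings).
#' @export
generate_dataset <- function(n_cells = 30, mixture = c(1, 1, 1) / 3,
                             frequency = 20, n_sweeps = 100,
                             sampling_rate = 2000, swim_rate = 0.4,
                             jitter_sd = 0.1, seed = 1) {
  if (abs(sum(mixture) - 1) > 1e-8) abort("`mixture` must sum to 1")
  if (length(mixture) != 3) abort("`mixture` has one proportion per group")
  sizes <- diff(round(cumsum(c(0, mixture)) * n_cells))
  if (n_cells < sum(mixture > 0)) abort("fewer cells than nonzero groups")
  protocol <- generate_protocol(frequency, n_sweeps)
  grid <- sim_grid(frequency, sampling_rate)
  presets <- .group_presets()
  lam <- grid$lambda_star

  cells <- withr::with_seed(seed, {
    groups <- rep(presets$group, sizes)
    jit <- function(x) x * exp(stats::rnorm(length(x), 0, jitter_sd))
    tibble(
      cell_id = sprintf("cell%02d", seq_len(n_cells)),
      group = groups,
      k1 = jit(presets$k1[groups]),
      k3 = jit(presets$k3[groups]),
      s0 = presets$s0[groups],
      target_rs = presets$target_rs[groups]
    )
  })
  cells$k2 <- .calibrate_stationary(cells$k3, cells$s0, cells$target_rs, lam)

  n_steps <- as.integer(round(protocol$session_length * sampling_rate))
  times <- (seq_len(n_steps) - 1) / sampling_rate
  # stimulus sample at each step: sinusoid restarting at each on-epoch
  s_vals <- numeric(n_steps)
  ep <- protocol$epochs
  for (i in seq_len(nrow(ep))) {
    sel <- times >= ep$start_s[i] & times < ep$end_s[i]
    s_vals[sel] <- sin(2 * pi * frequency * (times[sel] - ep$start_s[i]))
  }

  swims <- withr::with_seed(seed + 1, {
    purrr::map(seq_len(n_cells), function(i) {
      sw <- generate_swim_bouts(protocol$session_length, rate = swim_rate)
      sw$cell_id <- cells$cell_id[i]
      sw
    })
  })
  swim_tbl <- bind_rows(swims)

  # per-step CD indicator per cell
  cd_on <- matrix(FALSE, n_steps, n_cells)
  for (i in seq_len(n_cells)) {
    sw <- swims[[i]]
    for (j in seq_len(nrow(sw))) {
      cd_on[times >= sw$start_s[j] & times < sw$end_s[j], i] <- TRUE
    }
  }

  pc <- .clip01(cells$k3 * lam)
  spikes <- withr::with_seed(seed + 2, {
    pb_rest <- .clip01(cells$s0 * lam)
    init <- runif(n_cells) < pc / (pb_rest + pc)
    pb_step <- function(t) {
      k2_eff <- ifelse(cd_on[t, ], cells$k2, 1)
      .clip01((cells$k1 * s_vals[t] + k2_eff * cells$s0) * lam)
    }
    res <- .run_matrix(n_steps, n_cells, pb_step, pc, init)
    tibble(
      cell_id = cells$cell_id[res$unit],
      frequency_hz = frequency,
      time_s = times[res$step]
    )
  })

  stim_epochs <- ep[, c("kind", "start_s", "end_s")]
  epochs <- bind_rows(
    purrr::map(cells$cell_id, function(cid) {
      e <- stim_epochs
      e$cell_id <- cid
      e
    }),
    swim_tbl[, c("kind", "start_s", "end_s", "cell_id")]
  )
  labeled <- label_spikes(spikes, epochs, frequency)
  labeled$sweep <- floor(
    labeled$time_s / (protocol$on_duration + protocol$off_duration)
  ) + 1L

  structure(
    list(
      spikes = labeled,
      epochs = epochs,
      protocol = protocol,
      manifest = list(
        seed = seed, n_cells = n_cells, mixture = mixture,
        frequency = frequency, n_sweeps = n_sweeps,
        sampling_rate = sampling_rate, swim_rate = swim_rate,
        jitter_sd = jitter_sd, cells = cells
      )
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d cells, %g Hz, %d sweeps, %d spikes, %d swims\n",
    x$manifest$n_cells, x$manifest$frequency, x$manifest$n_sweeps,
    nrow(x$spikes), sum(x$epochs$kind == "swim")
  ))
  invisible(x)
}

#' Body-wave peak times at neuromast positions
#'
#' Quasi-steady traveling-wave toy model of undulatory swimming: the body
#' wave of wavelength `body_wavelength` (in body lengths) travels
#' rostro-caudally at the tail-beat frequency, and the moment of maximum
#' cupular deflection at a neuromast located at body position `x` in cycle
#' `c` is `t_peak = (c - 1 + x / body_wavelength) / f`. Rostral peaks
#' therefore precede caudal ones within each cycle by a constant offset
#' `dx / (body_wavelength * f)`.
#'
#' @param positions Neuromast positions as fractions of body length,
#'   sorted rostro-caudal (in `[0, 1]`).
#' @param tailbeat_hz Tail-beat frequency in Hz.
#' @param body_wavelength Body wavelength in body lengths (default 1).
#' @param n_cycles Number of tail-beat cycles.
#' @return A tibble with columns `position`, `cycle`, `t_peak`.
#' @examples
#' body_wave_peak_times(c(0, 0.5, 1), tailbeat_hz = 20, n_cycles = 2)
#' @export
body_wave_peak_times <- function(positions, tailbeat_hz, body_wavelength = 1,
                                 n_cycles = 1) {
  if (is.unsorted(positions)) abort("`positions` must be sorted rostro-caudal")
  if (any(positions < 0 | positions > 1)) abort("`positions` must lie in [0, 1]")
  stopifnot(tailbeat_hz > 0, body_wavelength > 0, n_cycles >= 1)
  tidyr::expand_grid(cycle = seq_len(n_cycles), position = positions) |>
    mutate(
      t_peak = (.data$cycle - 1 + .data$position / body_wavelength) /
        tailbeat_hz
    ) |>
    select("position", "cycle", "t_peak") |>
    arrange(.data$cycle, .data$position)
}
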