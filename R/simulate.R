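#' Per-step transition probabilities
#'
#' Evaluates the discrete-time transition matrix of the two-state sensor at
#' one or more stimulus values: `p_b = clip((k1 * s + k2 * s0) *
#' lambda_star, 0, 1)` (release/spike, sensitive to insensitive), `p_c =
#' clip(k3 * lambda_star, 0, 1)` (regeneration), with `p_a = 1 - p_b` and
#' `p_d = 1 - p_c`. Rows of the matrix sum to one by construction; clipping
#' absorbs out-of-range products.
#'
#' @param params A [sensor_params()].
#' @param stimulus_value Numeric vector of stimulus values `s(t)`.
#' @param grid A [sim_grid()].
#' @return A tibble with one row per stimulus value and columns `p_a`,
#'   `p_b`, `p_c`, `p_d`, plus `clipped` flagging values where clipping was
#'   active.
#' @examples
#' transition_probs(sensor_params(0, k3 = 4, s0 = 40), 0, sim_grid(20))
#' @export
transition_probs <- function(params, stimulus_value, grid) {
  stopifnot(inherits(params, "sensor_params"), inherits(grid, "sim_grid"))
  if (any(!is.finite(stimulus_value))) abort("`stimulus_value` must be finite")
  raw_b <- (params$k1 * stimulus_value + params$k2 * params$s0) *
    grid$lambda_star
  raw_c <- params$k3 * grid$lambda_star
  p_b <- .clip01(raw_b)
  p_c <- .clip01(raw_c)
  tibble(
    p_a = 1 - p_b,
    p_b = p_b,
    p_c = p_c,
    p_d = 1 - p_c,
    clipped = (raw_b != p_b) | (raw_c != p_c)
  )
}

#' Simulate a single stimulated sweep
#'
#' Runs one stochastic trajectory of the two-state sensor over a stimulus
#' trace. A spike is emitted at each sensitive-to-insensitive transition;
#' insensitive steps cannot spike. Spike times are `(step - 1) /
#' sampling_rate` so that a spike at step `t` shares the phase of the
#' stimulus sample that drove it.
#'
#' @param params A [sensor_params()].
#' @param stimulus A [stimulus_trace()] (or [make_stimulus()] output).
#' @param grid A [sim_grid()].
#' @param inhibition Optional per-step inhibition schedule (vector of `k2`
#'   values, same length as the stimulus); defaults to a constant
#'   `params$k2`.
#' @param seed Optional integer seed; identical seed and configuration give
#'   identical spike times.
#' @param return_state Logical; attach the per-step state trajectory
#'   (`1` sensitive, `2` insensitive) as attribute `"states"`?
#' @return A tibble with columns `step` and `time_s` (strictly increasing).
#' @examples
#' g <- sim_grid(20)
#' simulate_sweep(preset_sensor("nonadapting"), make_stimulus(g), g, seed = 1)
#' @export
simulate_sweep <- function(params, stimulus, grid, inhibition = NULL,
                           seed = NULL, return_state = FALSE) {
  stopifnot(
    inherits(params, "sensor_params"),
    inherits(stimulus, "stimulus_trace"),
    inherits(grid, "sim_grid")
  )
  s <- stimulus$values
  if (length(s) == 0) abort("empty stimulus")
  k2 <- inhibition %||% rep(params$k2, length(s))
  if (length(k2) != length(s)) {
    abort("`inhibition` schedule must match the stimulus length")
  }
  if (any(k2 < 0 | k2 > 1)) abort("inhibition values must lie in [0, 1]")
  pb <- .clip01((params$k1 * s + k2 * params$s0) * grid$lambda_star)
  pc <- .clip01(params$k3 * grid$lambda_star)
  run <- function() {
    n <- length(pb)
    state <- TRUE
    states <- if (return_state) integer(n) else NULL
    spikes <- logical(n)
    for (t in seq_len(n)) {
      if (return_state) states[t] <- if (state) 1L else 2L
      u <- runif(1)
      if (state) {
        if (u < pb[t]) {
          spikes[t] <- TRUE
          state <- FALSE
        }
      } else if (u < pc) {
        state <- TRUE
      }
    }
    list(spikes = which(spikes), states = states)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- tibble(
    step = res$spikes,
    time_s = (res$spikes - 1) / grid$sampling_rate
  )
  if (return_state) attr(out, "states") <- res$states
  out
}

#' Simulate a session of repeated sweeps
#'
#' A session is a sequence of sweeps, each composed of a stimulated/
#' inhibited active half (`n_wavelengths` stimulus wavelengths with the
#' sensor's `k2` applied) followed by a re-equilibration half of equal
#' length with the stimulus off. During re-equilibration the release term
#' is silenced (`requil = "silent"`, i.e. `k2 = 0`) so occupancy of the
#' sensitive state recovers; with `requil = "released"` inhibition is
#' instead lifted (`k2 = 1`), the configuration used to study rebound
#' spiking after release from inhibition. State carries across sweeps
#' within a chain, and the first `burn_in` sweeps of every chain are
#' flagged and excluded from downstream summaries.
#'
#' Long sessions can be parallelized over independent replicate chains
#' (`n_chains`): each chain runs `n_sweeps` sweeps including its own
#' burn-in, so `n_chains * (n_sweeps - burn_in)` sweeps are retained.
#'
#' @param params A [sensor_params()]; `params$k2` is the inhibition applied
#'   during the active half.
#' @param grid A [sim_grid()].
#' @param n_sweeps Sweeps per chain (including burn-in).
#' @param seed Optional integer seed.
#' @param stimulus Logical; present the sinusoidal stimulus during the
#'   active half? `FALSE` gives a spontaneous-only (inhibition-only)
#'   session.
#' @param rectified Passed to [make_stimulus()].
#' @param requil `"silent"` or `"released"` (see Details).
#' @param n_chains Number of independent replicate chains.
#' @param burn_in Number of initial sweeps per chain flagged as burn-in.
#' @param cell_id Identifier copied into the output.
#' @return A tibble of spikes of class `sensor_session` with columns
#'   `cell_id`, `frequency_hz`, `chain`, `sweep`, `step`, `time_s` (within
#'   sweep), `segment` (`"stim"`/`"requil"`), `burn_in`, `evoked`, `cd_on`,
#'   `interval_index` (1-based stimulus cycle, `NA` outside the active
#'   half), `stim_time`. Session metadata is stored in attributes.
#' @examples
#' g <- sim_grid(20)
#' s <- simulate_session(preset_sensor("adapting"), g, n_sweeps = 4, seed = 1)
#' @export
simulate_session <- function(params, grid, n_sweeps = 100, seed = NULL,
                             stimulus = TRUE, rectified = FALSE,
                             requil = c("silent", "released"),
                             n_chains = 1, burn_in = 2, cell_id = "sim") {
  stopifnot(inherits(params, "sensor_params"), inherits(grid, "sim_grid"))
  requil <- match.arg(requil)
  if (n_sweeps < 1) abort("`n_sweeps` must be >= 1")
  if (burn_in < 0) abort("`burn_in` must be >= 0")
  n_active <- as.integer(round(grid$n_wavelengths * grid$period_steps))
  s_vals <- if (stimulus) {
    make_stimulus(grid, rectified = rectified)$values
  } else {
    rep(0, n_active)
  }
  pb_active <- .pb_values(params, grid, s_vals)
  k2_requil <- if (requil == "silent") 0 else 1
  pb_requil <- rep(
    .clip01(k2_requil * params$s0 * grid$lambda_star),
    n_active
  )
  pb <- c(pb_active, pb_requil)
  pc <- .clip01(params$k3 * grid$lambda_star)
  run <- function() .run_template(pb, pc, n_sweeps, n_chains)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  in_active <- res$step <= n_active
  out <- tibble(
    cell_id = cell_id,
    frequency_hz = grid$frequency,
    chain = res$unit,
    sweep = res$sweep,
    step = res$step,
    time_s = (res$step - 1) / grid$sampling_rate,
    segment = ifelse(in_active, "stim", "requil"),
    burn_in = res$sweep <= burn_in,
    evoked = stimulus & in_active,
    cd_on = params$k2 < 1 & in_active,
    interval_index = ifelse(
      in_active,
      (res$step - 1L) %/% grid$period_steps + 1L,
      NA_integer_
    ),
    stim_time = ifelse(in_active, (res$step - 1) / grid$sampling_rate, NA_real_)
  )
  out <- out[order(out$chain, out$sweep, out$step), ]
  structure(
    out,
    class = c("sensor_session", class(out)),
    params = params,
    grid = grid,
    n_sweeps = n_sweeps,
    n_chains = n_chains,
    burn_in = burn_in,
    stimulus = stimulus,
    requil = requil
  )
}

#' Per-sweep spike counts of a session
#'
#' Tabulates spikes per sweep (zeros included) for one segment of a
#' [simulate_session()] result, dropping burn-in sweeps by default.
#'
#' @param session A `sensor_session`.
#' @param segment `"stim"` (active half) or `"requil"`.
#' @param drop_burn_in Exclude each chain's burn-in sweeps?
#' @return A tibble with columns `chain`, `sweep`, `n`.
#' @export
sweep_counts <- function(session, segment = "stim", drop_burn_in = TRUE) {
  stopifnot(inherits(session, "sensor_session"))
  n_chains <- attr(session, "n_chains")
  n_sweeps <- attr(session, "n_sweeps")
  burn <- if (drop_burn_in) attr(session, "burn_in") else 0L
  if (n_sweeps <= burn) {
    return(tibble(chain = integer(), sweep = integer(), n = integer()))
  }
  keep <- session$segment == segment & (!drop_burn_in | !session$burn_in)
  seg <- session[keep, c("chain", "sweep")]
  full <- tidyr::expand_grid(
    chain = seq_len(n_chains),
    sweep = seq.int(burn + 1L, n_sweeps)
  )
  counted <- dplyr::count(seg, .data$chain, .data$sweep, name = "n")
  out <- left_join(full, counted, by = c("chain", "sweep"))
  out$n[is.na(out$n)] <- 0L
  out
}

#' Expected spike count by exact state propagation
#'
#' Propagates the two-state occupancy distribution step by step, starting
#' sensitive, and accumulates the expected spike count `sum_t P(sensitive
#' at t) * p_b(t)`. Intended as the exact oracle against which Monte Carlo
#' means are checked, so the number of steps is capped.
#'
#' @param params A [sensor_params()].
#' @param stimulus A [stimulus_trace()].
#' @param grid A [sim_grid()].
#' @param n_steps Number of steps to propagate (default: the stimulus
#'   length, at most `cap`).
#' @param cap Maximum number of steps allowed.
#' @return The expected spike count (a single number).
#' @examples
#' g <- sim_grid(20)
#' st <- stimulus_trace(rep(1, 10), g)
#' enumerate_expected_spikes(preset_sensor("nonadapting"), st, g)
#' @export
enumerate_expected_spikes <- function(params, stimulus, grid, n_steps = NULL,
                                      cap = 16) {
  stopifnot(
    inherits(params, "sensor_params"),
    inherits(stimulus, "stimulus_trace"),
    inherits(grid, "sim_grid")
  )
  n_steps <- n_steps %||% min(length(stimulus$values), cap)
  if (n_steps > cap) {
    abort(sprintf("`n_steps` exceeds the exact-propagation cap (%d)", cap))
  }
  pb <- .pb_values(params, grid, stimulus$values[seq_len(n_steps)])
  pc <- .clip01(params$k3 * grid$lambda_star)
  p <- 1
  total <- 0
  for (t in seq_len(n_steps)) {
    total <- total + p * pb[t]
    p <- p * (1 - pb[t]) + (1 - p) * pc
  }
  total
}

#' Classify a parameter set as adapting or nonadapting
#'
#' Computes the exact expected per-cycle evoked spike counts of the
#' uninhibited (`k2 = 1`) steady-state session by propagating the
#' occupancy distribution through the periodic sweep template, and labels
#' the set `"adapting"` when the mean count over the last two stimulus
#' cycles falls below `tau` times the mean over the first two. The label is
#' assigned empirically from the dynamics rather than from published
#' labels.
#'
#' @param params A [sensor_params()] (its `k2` is ignored; classification
#'   uses the uninhibited sensor).
#' @param grid A [sim_grid()].
#' @param tau Adaptation threshold on the last-2/first-2 count ratio.
#' @param rectified Passed to [make_stimulus()].
#' @param requil Re-equilibration mode, as in [simulate_session()].
#' @return `"adapting"` or `"nonadapting"`, with the expected per-cycle
#'   counts attached as attribute `"cycle_counts"`.
#' @examples
#' classify_sensor(preset_sensor("adapting"), sim_grid(20))
#' @export
classify_sensor <- function(params, grid, tau = 0.5, rectified = FALSE,
                            requil = c("silent", "released")) {
  stopifnot(inherits(params, "sensor_params"), inherits(grid, "sim_grid"))
  requil <- match.arg(requil)
  uninhibited <- sensor_params(params$k1, params$k3, params$s0, k2 = 1)
  n_active <- as.integer(round(grid$n_wavelengths * grid$period_steps))
  s_vals <- make_stimulus(grid, rectified = rectified)$values
  pb_active <- .pb_values(uninhibited, grid, s_vals)
  k2_requil <- if (requil == "silent") 0 else 1
  pb <- c(
    pb_active,
    rep(.clip01(k2_requil * params$s0 * grid$lambda_star), n_active)
  )
  pc <- .clip01(params$k3 * grid$lambda_star)
  exp_sweep <- .expected_sweep(pb, pc)
  e_active <- exp_sweep$e[seq_len(n_active)]
  cycle <- (seq_len(n_active) - 1L) %/% grid$period_steps + 1L
  cyc <- tapply(e_active, cycle, sum)
  n_cyc <- length(cyc)
  if (n_cyc < 4) abort("need at least 4 stimulus cycles to classify")
  first2 <- mean(cyc[1:2])
  last2 <- mean(cyc[(n_cyc - 1):n_cyc])
  if (first2 <= 0) abort("undriven sensor: no expected spikes in the first cycles")
  label <- if (last2 < tau * first2) "adapting" else "nonadapting"
  structure(label, cycle_counts = as.numeric(cyc))
}
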