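#' Calibrate inhibition strength against the spontaneous suppression ratio
#'
#' Nonlinearities of the two-state sensor make the inhibition constant `k2`
#' and the observed spontaneous suppression ratio `R_S` (spontaneous rate
#' with inhibition / without) unequal, so inhibition levels are expressed
#' as *observed* `R_S` and `k2` is solved for. The expected spontaneous
#' rate is computed exactly (closed-form occupancy recursion), making the
#' calibration deterministic; Monte Carlo sessions at the returned `k2`
#' reproduce the target ratio up to sampling error.
#'
#' Two measurement contexts are supported: `"session"` matches the
#' active/re-equilibration sweep protocol of [simulate_session()] (rates
#' measured over the active half at periodic steady state), and
#' `"stationary"` uses the long-run stationary rate under constant
#' conditions (appropriate for swim-bout simulations).
#'
#' @param params A [sensor_params()] (its `k2` is ignored).
#' @param grid A [sim_grid()].
#' @param target_rs Target spontaneous ratio in `(0, 1]`.
#' @param context `"session"` or `"stationary"`.
#' @param requil Re-equilibration mode of the session protocol.
#' @param tol Bisection tolerance on the achieved ratio.
#' @return The calibrated `k2` value.
#' @examples
#' g <- sim_grid(20)
#' calibrate_inhibition(preset_sensor("nonadapting"), g, target_rs = 0.1)
#' @export
calibrate_inhibition <- function(params, grid, target_rs,
                                 context = c("session", "stationary"),
                                 requil = c("silent", "released"),
                                 tol = 1e-10) {
  stopifnot(inherits(params, "sensor_params"), inherits(grid, "sim_grid"))
  context <- match.arg(context)
  requil <- match.arg(requil)
  if (!is.numeric(target_rs) || target_rs <= 0 || target_rs > 1) {
    abort("`target_rs` must lie in (0, 1]")
  }
  if (params$s0 <= 0) {
    abort("cannot calibrate a sensor without spontaneous activity (s0 = 0)")
  }
  if (target_rs == 1) {
    return(1)
  }
  lam <- grid$lambda_star
  pc <- .clip01(params$k3 * lam)
  if (context == "stationary") {
    # stationary rate pb * pc / (pb + pc); solve ratio = target in closed form
    pbu <- .clip01(params$s0 * lam)
    pbi <- target_rs * pbu * pc / ((1 - target_rs) * pbu + pc)
    return(pbi / (params$s0 * lam))
  }
  n_half <- as.integer(round(grid$n_wavelengths * grid$period_steps))
  pb_r <- if (requil == "silent") 0 else .clip01(params$s0 * lam)
  count_at <- function(k2) {
    .spont_count_session(
      .clip01(k2 * params$s0 * lam), pb_r, pc, n_half, n_half
    )
  }
  ref <- count_at(1)
  if (ref <= 0) abort("reference spontaneous rate is zero; cannot calibrate")
  g <- function(k2) count_at(k2) / ref - target_rs
  lo <- 0
  hi <- 1
  if (g(hi) < 0) abort("`target_rs` unreachable within k2 in [0, 1]")
  root <- stats::uniroot(g, c(lo, hi), tol = tol)$root
  min(max(root, 0), 1)
}

#' Monte Carlo inhibition sweep: measured R_S, R_E and their ratio
#'
#' For each target spontaneous suppression level, calibrates `k2`
#' ([calibrate_inhibition()]), simulates spontaneous-only and stimulated
#' sessions with and without inhibition, and measures the spontaneous and
#' evoked inhibition ratios `R_S` and `R_E` (active-half rates, CD ON /
#' CD OFF) with delta-method standard errors. This is the procedure behind
#' the adapting/nonadapting divergence analysis: nonadapting sensors keep
#' `R_E / R_S = 1` at every level, adapting sensors show `R_E / R_S > 1`
#' whenever `R_S < 1`.
#'
#' @param params A [sensor_params()] (uninhibited reference taken at
#'   `k2 = 1`).
#' @param grid A [sim_grid()].
#' @param targets Vector of target `R_S` values in `(0, 1]`.
#' @param n_sweeps Retained (post burn-in) sweeps per session.
#' @param n_chains Replicate chains used to parallelize each session.
#' @param seed Integer seed (sessions receive derived sub-seeds).
#' @param requil Re-equilibration mode, see [simulate_session()].
#' @return A tibble with one row per level: `target_rs`, `k2`, measured
#'   `r_s`, `r_e` (with `se_rs`, `se_re`), `ratio` = `r_e / r_s` (with
#'   `se_ratio`), `retention_pct` = 100 * inhibited / uninhibited evoked
#'   count, and the per-condition mean counts.
#' @examples
#' \donttest{
#' g <- sim_grid(20)
#' inhibition_sweep(preset_sensor("nonadapting"), g,
#'   targets = c(0.5, 1), n_sweeps = 200, n_chains = 50, seed = 1
#' )
#' }
#' @export
inhibition_sweep <- function(params, grid, targets = c(0.1, 0.25, 0.5, 0.75, 1),
                             n_sweeps = 2000, n_chains = 250, seed = NULL,
                             requil = c("silent", "released")) {
  stopifnot(inherits(params, "sensor_params"), inherits(grid, "sim_grid"))
  requil <- match.arg(requil)
  seed <- seed %||% sample.int(1e6, 1)
  burn <- 2
  per_chain <- ceiling(n_sweeps / n_chains) + burn
  mean_se <- function(counts) {
    m <- mean(counts$n)
    list(mean = m, se = sd(counts$n) / sqrt(nrow(counts)))
  }
  run <- function(k2, stim, sub) {
    p <- sensor_params(params$k1, params$k3, params$s0, k2 = k2)
    s <- simulate_session(
      p, grid,
      n_sweeps = per_chain, seed = seed + sub, stimulus = stim,
      requil = requil, n_chains = n_chains, burn_in = burn
    )
    mean_se(sweep_counts(s))
  }
  ref_spont <- run(1, FALSE, 1L)
  ref_evoked <- run(1, TRUE, 2L)
  rows <- purrr::imap(targets, function(tg, i) {
    k2 <- calibrate_inhibition(params, grid, tg, requil = requil)
    spont <- run(k2, FALSE, 10L * i + 3L)
    evoked <- run(k2, TRUE, 10L * i + 4L)
    rs <- spont$mean / ref_spont$mean
    re <- evoked$mean / ref_evoked$mean
    rel2 <- function(x) (x$se / x$mean)^2
    se_rs <- rs * sqrt(rel2(spont) + rel2(ref_spont))
    se_re <- re * sqrt(rel2(evoked) + rel2(ref_evoked))
    ratio <- re / rs
    se_ratio <- ratio * sqrt(
      rel2(spont) + rel2(ref_spont) + rel2(evoked) + rel2(ref_evoked)
    )
    tibble(
      target_rs = tg, k2 = k2,
      r_s = rs, se_rs = se_rs,
      r_e = re, se_re = se_re,
      ratio = ratio, se_ratio = se_ratio,
      retention_pct = 100 * re,
      n_kept = n_chains * (per_chain - burn),
      spont_count = spont$mean, evoked_count = evoked$mean,
      spont_ref = ref_spont$mean, evoked_ref = ref_evoked$mean
    )
  })
  bind_rows(rows)
}
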