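#' Classify swim bouts against stimulus epochs
#'
#' Pairs every swim bout with an equal-duration post-swim window and
#' classifies the bout as falling fully `"within"` a stimulus-on epoch,
#' fully `"outside"` all of them, or `"straddling"` a boundary. Straddling
#' bouts are excluded from the normalized time courses.
#'
#' @param swims A tibble of swim epochs (`cell_id` optional, `start_s`,
#'   `end_s`).
#' @param stim_epochs A tibble of stimulus epochs (`start_s`, `end_s`),
#'   typically filtered from a [generate_protocol()] epoch table.
#' @return `swims` with `post_start_s`, `post_end_s`, `duration`,
#'   `classification` added.
#' @export
classify_swims <- function(swims, stim_epochs) {
  swims <- as_tibble(swims)
  stim <- as_tibble(stim_epochs)
  dur <- swims$end_s - swims$start_s
  classification <- vapply(seq_len(nrow(swims)), function(i) {
    s <- swims$start_s[i]
    e <- swims$end_s[i]
    within <- any(stim$start_s <= s & e <= stim$end_s)
    outside <- all(e <= stim$start_s | s >= stim$end_s)
    if (within) "within" else if (outside) "outside" else "straddling"
  }, character(1))
  swims$duration <- dur
  swims$post_start_s <- swims$end_s
  swims$post_end_s <- swims$end_s + dur
  swims$classification <- classification
  swims
}

#' Swim-normalized response time course
#'
#' Maps spikes around each eligible swim bout onto relative time: the bout
#' itself spans `[0, 1]` and the equal-duration post-swim window spans
#' `(1, 2]`, so bouts of very different durations contribute on a common
#' axis. Per-bin summaries are means weighted by the number of
#' contributing swims; evoked analyses use only swims falling entirely
#' within a stimulus epoch, spontaneous analyses only swims entirely
#' outside. For evoked responses per-bin phase statistics (quantiles,
#' vector strength, gain) are also reported; for spontaneous responses the
#' per-bin quantity is a spike *rate*, since each bout stretches real time
#' by its own duration.
#'
#' @param labeled A labeled spike table from [label_spikes()].
#' @param swims A classified swim table from [classify_swims()].
#' @param n_bins Number of bins per unit of relative time (total `2 *
#'   n_bins` bins over `[0, 2]`).
#' @param response `"evoked"` or `"spontaneous"`.
#' @param frequency Stimulus frequency in Hz (needed for evoked phase
#'   statistics; defaults to the table's `frequency_hz`).
#' @return A tibble with one row per bin: `u_mid` (relative time),
#'   `n_swims`, `n_spikes`, `mean_count` (evoked) or `rate` (spontaneous),
#'   and for evoked bins `q10`, `q50`, `q90`, `vs`, `gain`.
#' @export
swim_normalized_timecourse <- function(labeled, swims, n_bins = 10,
                                       response = c("evoked", "spontaneous"),
                                       frequency = NULL) {
  response <- match.arg(response)
  labeled <- as_tibble(labeled)
  swims <- as_tibble(swims)
  if (!"classification" %in% names(swims)) {
    abort("`swims` must be classified with classify_swims()")
  }
  want <- if (response == "evoked") "within" else "outside"
  eligible <- swims[swims$classification == want, ]
  if (nrow(eligible) == 0) abort("no eligible swims")
  has_cell <- "cell_id" %in% names(eligible)
  frequency <- frequency %||% unique(labeled$frequency_hz) %||% NA_real_
  period <- 1 / frequency

  per_swim <- purrr::map(seq_len(nrow(eligible)), function(i) {
    sw <- eligible[i, ]
    d <- labeled
    if (has_cell) d <- d[d$cell_id == sw$cell_id, ]
    d <- d[d$evoked == (response == "evoked"), ]
    inwin <- d$time_s >= sw$start_s & d$time_s < sw$post_end_s
    d <- d[inwin, ]
    u <- (d$time_s - sw$start_s) / sw$duration
    tibble(
      swim = i, u = u, time_s = d$time_s,
      stim_time = if (response == "evoked") d$stim_time else NA_real_,
      duration = sw$duration
    )
  })
  spk <- bind_rows(per_swim)
  edges <- seq(0, 2, length.out = 2 * n_bins + 1)
  n_swims <- nrow(eligible)
  bins <- tibble(
    bin = seq_len(2 * n_bins),
    u_lo = edges[-length(edges)],
    u_hi = edges[-1]
  )
  bins$u_mid <- (bins$u_lo + bins$u_hi) / 2
  rows <- purrr::map(seq_len(nrow(bins)), function(b) {
    sel <- spk$u >= bins$u_lo[b] & spk$u < bins$u_hi[b]
    d <- spk[sel, ]
    n_spikes <- nrow(d)
    # every eligible swim spans every bin, so all contribute exposure
    counts <- tabulate(factor(d$swim, levels = seq_len(n_swims)), n_swims)
    res <- tibble(
      bin = bins$bin[b], u_mid = bins$u_mid[b],
      n_swims = n_swims, n_spikes = n_spikes,
      mean_count = mean(counts)
    )
    if (response == "spontaneous") {
      bw <- bins$u_hi[b] - bins$u_lo[b]
      res$rate <- mean(counts / (bw * eligible$duration))
    } else if (n_spikes > 0 && is.finite(period)) {
      theta <- 2 * pi * ((d$stim_time / period) %% 1)
      q <- phase_quantiles(theta, center = pi / 2)
      vs <- vector_strength(theta)
      res$q10 <- q[[1]]
      res$q50 <- q[[2]]
      res$q90 <- q[[3]]
      res$vs <- vs
      res$gain <- response_gain(mean(counts), vs)
    } else {
      res$q10 <- NA_real_
      res$q50 <- NA_real_
      res$q90 <- NA_real_
      res$vs <- NA_real_
      res$gain <- NA_real_
    }
    res
  })
  bind_rows(rows)
}
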