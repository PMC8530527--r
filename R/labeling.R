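#' Label spikes by stimulus and motor state
#'
#' Classifies every spike on two independent axes: `evoked` if it falls
#' within a stimulus-on epoch (spontaneous otherwise) and `cd_on` if it
#' falls within a swim bout (the corollary discharge is active strictly
#' during swims). Epoch boundaries are half-open `[start, end)`. Evoked
#' spikes additionally receive the 1-based index of the stimulus cycle
#' within their epoch and `stim_time`, the time since epoch onset.
#'
#' @param spikes A tibble with columns `cell_id` and `time_s` (a bare
#'   numeric vector is accepted for a single cell).
#' @param epochs An epoch table with columns `cell_id`, `kind`
#'   (`"stimulus"` or `"swim"`), `start_s`, `end_s`. Epochs of the same
#'   kind must not overlap within a cell.
#' @param frequency Stimulus frequency in Hz, used for cycle indices.
#' @return The spike table with columns `evoked`, `cd_on`, `stim_time`,
#'   `interval_index` added.
#' @export
label_spikes <- function(spikes, epochs, frequency) {
  if (is.numeric(spikes)) {
    spikes <- tibble(cell_id = "cell", time_s = spikes)
  }
  spikes <- as_tibble(spikes)
  epochs <- as_tibble(epochs)
  stopifnot(
    all(c("cell_id", "time_s") %in% names(spikes)),
    all(c("kind", "start_s", "end_s") %in% names(epochs))
  )
  if (!"cell_id" %in% names(epochs)) {
    epochs$cell_id <- spikes$cell_id[1]
  }
  if (any(epochs$end_s <= epochs$start_s)) abort("epochs must have end > start")
  period <- 1 / frequency

  check_overlap <- function(e) {
    e <- e[order(e$start_s), ]
    if (nrow(e) > 1 && any(e$start_s[-1] < e$end_s[-nrow(e)])) {
      abort(sprintf("overlapping %s epochs within a cell", e$kind[1]))
    }
    e
  }
  # validate all cells up front, including cells without spikes
  for (cid in unique(epochs$cell_id)) {
    for (kd in unique(epochs$kind)) {
      check_overlap(epochs[epochs$cell_id == cid & epochs$kind == kd, ])
    }
  }
  match_epoch <- function(t, e) {
    # index of containing epoch under [start, end), NA if none
    if (nrow(e) == 0) {
      return(rep(NA_integer_, length(t)))
    }
    i <- findInterval(t, e$start_s)
    inside <- i >= 1 & t < e$end_s[pmax(i, 1)]
    ifelse(inside, i, NA_integer_)
  }

  out <- spikes |>
    group_by(.data$cell_id) |>
    dplyr::group_modify(function(d, key) {
      e_cell <- epochs[epochs$cell_id == key$cell_id[1], ]
      stim <- check_overlap(e_cell[e_cell$kind == "stimulus", ])
      swim <- check_overlap(e_cell[e_cell$kind == "swim", ])
      si <- match_epoch(d$time_s, stim)
      wi <- match_epoch(d$time_s, swim)
      d$evoked <- !is.na(si)
      d$cd_on <- !is.na(wi)
      d$stim_time <- ifelse(d$evoked, d$time_s - stim$start_s[si], NA_real_)
      # small epsilon so cycle boundaries are robust to float round-off
      d$interval_index <- ifelse(
        d$evoked,
        as.integer(floor(d$stim_time / period + 1e-9)) + 1L,
        NA_integer_
      )
      d
    }) |>
    ungroup()
  out
}

# total overlap length between two sets of disjoint intervals
.overlap_length <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(0)
  }
  tot <- 0
  for (i in seq_len(nrow(a))) {
    tot <- tot + sum(pmax(
      0, pmin(a$end_s[i], b$end_s) - pmax(a$start_s[i], b$start_s)
    ))
  }
  tot
}

#' Evoked and spontaneous inhibition ratios
#'
#' Computes, per cell, the spontaneous and evoked activity ratios `R_S`
#' and `R_E` (rate with corollary discharge ON / rate with CD OFF). Rates
#' are spikes per unit *exposure time* in each cell of the evoked/
#' spontaneous x ON/OFF label grid, with exposure times derived from the
#' stimulus and swim epoch tables (ON and OFF exposures generally differ,
#' so raw counts would be biased).
#'
#' @param labeled A labeled spike table from [label_spikes()].
#' @param epochs The epoch table used for labeling.
#' @param total_duration Recording duration in seconds per cell (default:
#'   the largest epoch end or spike time).
#' @return A tibble with one row per cell: exposures, counts, rates,
#'   `r_s`, `r_e`.
#' @export
activity_ratios <- function(labeled, epochs, total_duration = NULL) {
  labeled <- as_tibble(labeled)
  epochs <- as_tibble(epochs)
  if (!"cell_id" %in% names(epochs)) epochs$cell_id <- labeled$cell_id[1]
  cells <- unique(labeled$cell_id)
  rows <- purrr::map(cells, function(cid) {
    d <- labeled[labeled$cell_id == cid, ]
    e <- epochs[epochs$cell_id == cid, ]
    stim <- e[e$kind == "stimulus", ]
    swim <- e[e$kind == "swim", ]
    total <- total_duration %||%
      max(c(e$end_s, d$time_s), na.rm = TRUE)
    t_stim <- sum(stim$end_s - stim$start_s)
    t_swim <- sum(swim$end_s - swim$start_s)
    t_ev_on <- .overlap_length(stim, swim)
    exposure <- c(
      ev_on = t_ev_on,
      ev_off = t_stim - t_ev_on,
      sp_on = t_swim - t_ev_on,
      sp_off = total - t_stim - (t_swim - t_ev_on)
    )
    if (any(exposure[c("ev_off", "sp_off")] <= 0)) {
      abort("zero CD-OFF exposure; ratios undefined")
    }
    counts <- c(
      ev_on = sum(d$evoked & d$cd_on),
      ev_off = sum(d$evoked & !d$cd_on),
      sp_on = sum(!d$evoked & d$cd_on),
      sp_off = sum(!d$evoked & !d$cd_on)
    )
    rates <- counts / exposure
    if (rates[["ev_off"]] == 0 || rates[["sp_off"]] == 0) {
      abort("zero CD-OFF rate; ratios undefined")
    }
    tibble(
      cell_id = cid,
      exposure_ev_on = exposure[["ev_on"]], exposure_ev_off = exposure[["ev_off"]],
      exposure_sp_on = exposure[["sp_on"]], exposure_sp_off = exposure[["sp_off"]],
      n_ev_on = counts[["ev_on"]], n_ev_off = counts[["ev_off"]],
      n_sp_on = counts[["sp_on"]], n_sp_off = counts[["sp_off"]],
      r_s = rates[["sp_on"]] / rates[["sp_off"]],
      r_e = rates[["ev_on"]] / rates[["ev_off"]]
    )
  })
  bind_rows(rows)
}

#' Per-cycle evoked spike counts
#'
#' Mean CD-OFF evoked spike count per stimulus cycle (burn-in sweeps
#' excluded), the input to [adaptation_index()].
#'
#' @param labeled A labeled spike table with `evoked`, `cd_on`,
#'   `interval_index` and optionally `burn_in` columns.
#' @param n_intervals Number of cycles to report (default: max observed).
#' @return A tibble with columns `interval_index`, `n`.
#' @export
interval_counts <- function(labeled, n_intervals = NULL) {
  labeled <- as_tibble(labeled)
  if (!"burn_in" %in% names(labeled)) labeled$burn_in <- FALSE
  ev <- filter(
    labeled, .data$evoked, !.data$cd_on, !.data$burn_in,
    !is.na(.data$interval_index)
  )
  n_intervals <- n_intervals %||% max(ev$interval_index, 1L)
  counts <- tabulate(ev$interval_index, nbins = n_intervals)
  tibble(interval_index = seq_len(n_intervals), n = counts)
}

#' Adaptation index from first and last stimulus cycles
#'
#' The mean response over the first two stimulus cycles relative to the
#' mean over the last two, reported in both orientations (First/Last and
#' Last/First). Averaging two cycles at each end is less noisy than using
#' single cycles.
#'
#' @param counts A tibble with columns `interval_index`, `n` (see
#'   [interval_counts()]) or a numeric vector of per-cycle counts in cycle
#'   order.
#' @return A tibble with columns `first2`, `last2`, `first_last`,
#'   `last_first`. When the last-two mean is zero the ratios are `NA`
#'   (flagged undefined).
#' @examples
#' adaptation_index(c(10, 8, 5, 4, 3, 3))
#' @export
adaptation_index <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- counts$n[order(counts$interval_index)]
  }
  m <- length(counts)
  if (m < 4) abort("need at least 4 stimulus cycles")
  first2 <- mean(counts[1:2])
  last2 <- mean(counts[(m - 1):m])
  tibble(
    first2 = first2,
    last2 = last2,
    first_last = if (last2 > 0) first2 / last2 else NA_real_,
    last_first = if (first2 > 0) last2 / first2 else NA_real_
  )
}
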