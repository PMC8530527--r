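test_that("swims classify as within, outside or straddling", {
  stim <- tibble::tibble(start_s = c(1, 4), end_s = c(2, 5))
  swims <- tibble::tibble(
    cell_id = "c1",
    start_s = c(1.1, 2.5, 1.9),
    end_s = c(1.4, 2.8, 2.2)
  )
  cls <- classify_swims(swims, stim)
  expect_equal(cls$classification, c("within", "outside", "straddling"))
  expect_equal(cls$post_end_s - cls$post_start_s, cls$duration)
})

test_that("spikes map onto relative swim time", {
  stim <- tibble::tibble(start_s = 10, end_s = 20) # swims all outside
  swims <- classify_swims(
    tibble::tibble(cell_id = "c1", start_s = 1, end_s = 1.5), stim
  )
  sp <- tibble::tibble(
    cell_id = "c1", time_s = c(1.25, 1.75),
    evoked = FALSE, cd_on = c(TRUE, FALSE),
    stim_time = NA_real_, interval_index = NA_integer_
  )
  tc <- swim_normalized_timecourse(sp, swims,
    n_bins = 2, response = "spontaneous", frequency = 20
  )
  # spike at 0.25 s into a 0.5-s swim -> u = 0.5; post-swim spike -> u = 1.5
  expect_equal(tc$n_spikes[tc$u_mid == 0.75], 1)
  expect_equal(tc$n_spikes[tc$u_mid == 1.75], 1)
  expect_equal(sum(tc$n_spikes), 2)
})

test_that("identical relative patterns at different durations give identical curves", {
  stim <- tibble::tibble(start_s = 0, end_s = 100)
  swims <- classify_swims(
    tibble::tibble(cell_id = "c1", start_s = c(1, 10), end_s = c(1.4, 10.8)),
    stim
  )
  rel <- c(0.11, 0.31, 0.63, 1.21, 1.81)
  sp <- tibble::tibble(
    cell_id = "c1",
    time_s = c(1 + 0.4 * rel, 10 + 0.8 * rel),
    evoked = TRUE, cd_on = FALSE,
    stim_time = time_s, interval_index = 1L
  )
  tc <- swim_normalized_timecourse(sp, swims, n_bins = 5, frequency = 20)
  counts <- tc$mean_count
  # both swims contribute the same per-bin counts
  per_bin <- table(findInterval(rel, seq(0, 2, by = 0.2), rightmost.closed = TRUE))
  expect_equal(sum(tc$n_spikes), 10)
  expect_equal(tc$n_swims, rep(2, 10))
  expect_equal(counts, tabulate(findInterval(rel, seq(0, 2, by = 0.2)), 10))
})

test_that("straddling swims are excluded and empty selections error", {
  stim <- tibble::tibble(start_s = 1, end_s = 2)
  swims <- classify_swims(
    tibble::tibble(cell_id = "c1", start_s = 1.9, end_s = 2.1), stim
  )
  sp <- tibble::tibble(
    cell_id = "c1", time_s = 1.95, evoked = TRUE, cd_on = TRUE,
    stim_time = 0.95, interval_index = 1L
  )
  expect_error(
    swim_normalized_timecourse(sp, swims, response = "evoked", frequency = 20),
    "no eligible"
  )
})

test_that("inhibition during swims produces a post-swim spontaneous peak", {
  # simulated session: strong inhibition during the swim, release after
  g <- sim_grid(20)
  p <- preset_sensor("adapting")
  k2 <- calibrate_inhibition(p, g, 0.1)
  ses <- simulate_session(
    sensor_params(p$k1, p$k3, p$s0, k2 = k2), g,
    n_sweeps = 10, seed = 61, stimulus = FALSE,
    requil = "released", n_chains = 60
  )
  # treat each sweep's active (inhibited) half as a "swim" of 1 s
  sp <- tibble::tibble(
    cell_id = "c1",
    time_s = (ses$sweep - 1) * 2 + ses$time_s + (ses$chain - 1) * 1e4,
    evoked = FALSE, cd_on = ses$segment == "stim",
    stim_time = NA_real_, interval_index = NA_integer_
  )
  swims <- dplyr::bind_rows(lapply(unique(ses$chain), function(ch) {
    tibble::tibble(
      cell_id = "c1",
      start_s = (2:9) * 2 + (ch - 1) * 1e4,
      end_s = (2:9) * 2 + 1 + (ch - 1) * 1e4
    )
  }))
  swims <- classify_swims(swims, tibble::tibble(start_s = -2, end_s = -1))
  tc <- swim_normalized_timecourse(sp, swims,
    n_bins = 5, response = "spontaneous", frequency = 20
  )
  in_swim <- mean(tc$rate[tc$u_mid < 1])
  first_post <- tc$rate[6]
  expect_gt(first_post, 3 * in_swim)
})
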