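test_that("undriven sensors never spike and empty stimuli error", {
  g <- sim_grid(20)
  silent <- sensor_params(0, k3 = 1, s0 = 0)
  sw <- simulate_sweep(silent, make_stimulus(g), g, seed = 1)
  expect_equal(nrow(sw), 0)
  expect_error(
    simulate_sweep(silent, structure(list(values = numeric(0)),
      class = "stimulus_trace"
    ), g),
    "empty"
  )
})

test_that("identical seeds reproduce spike times exactly", {
  g <- sim_grid(20)
  p <- preset_sensor("nonadapting")
  a <- simulate_session(p, g, n_sweeps = 5, seed = 99, n_chains = 3)
  b <- simulate_session(p, g, n_sweeps = 5, seed = 99, n_chains = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_session(p, g, n_sweeps = 5, seed = 100, n_chains = 3)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("instant regeneration approaches the Bernoulli spike count", {
  # p_c = 1: regeneration on the step after each spike, so the exact mean
  # over n steps is n * p_b * p_c / (p_b + p_c) = n * p_b / (1 + p_b),
  # which approaches the independent-Bernoulli value n * p_b as p_b -> 0
  g <- sim_grid(20, 2000)
  p <- sensor_params(0, k3 = 200, s0 = 10) # p_b = 0.1, p_c = 1
  n_steps <- 400
  st <- stimulus_trace(rep(0, n_steps), g)
  counts <- withr::with_seed(7, {
    replicate(500, nrow(simulate_sweep(p, st, g)))
  })
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - n_steps * 0.1 / 1.1), 3 * se)
  # small-release limit: within 1% of n * p_b
  p2 <- sensor_params(0, k3 = 200, s0 = 0.5) # p_b = 0.005
  exact <- enumerate_expected_spikes(p2, stimulus_trace(rep(0, 16), g), g)
  expect_equal(exact, 16 * 0.005, tolerance = 0.01)
})

test_that("sweeps respect the single-spike-per-step contract", {
  g <- sim_grid(20)
  p <- preset_sensor("nonadapting")
  sw <- simulate_sweep(p, make_stimulus(g), g, seed = 3)
  expect_false(any(duplicated(sw$step)))
  expect_true(all(diff(sw$time_s) > 0))
})

test_that("sessions flag burn-in and segment structure correctly", {
  g <- sim_grid(20)
  p <- preset_sensor("nonadapting")
  ses <- simulate_session(p, g, n_sweeps = 2, seed = 5)
  expect_true(all(ses$burn_in))
  expect_equal(nrow(sweep_counts(ses)), 0)
  # released re-equilibration restores spontaneous drive, so both
  # segments carry spikes
  ses4 <- simulate_session(p, g, n_sweeps = 4, seed = 5, requil = "released")
  expect_setequal(unique(ses4$segment), c("stim", "requil"))
  # active-half spikes carry interval indices, re-equilibration spikes none
  expect_true(all(!is.na(ses4$interval_index[ses4$segment == "stim"])))
  expect_true(all(is.na(ses4$interval_index[ses4$segment == "requil"])))
  cnt <- sweep_counts(ses4)
  expect_equal(nrow(cnt), 2) # sweeps 3 and 4
})

test_that("expected spike counts by exact propagation match hand results", {
  g <- sim_grid(20, 2000)
  # single step, p_b = 0.3
  p1 <- sensor_params(0, k3 = 1, s0 = 30)
  st1 <- stimulus_trace(0, g)
  expect_equal(enumerate_expected_spikes(p1, st1, g), 0.3)
  # two steps, p_b = 0.5, p_c ~ 0: 0.5 + 0.25
  p2 <- sensor_params(0, k3 = 1e-9, s0 = 50)
  st2 <- stimulus_trace(c(0, 0), g)
  expect_equal(enumerate_expected_spikes(p2, st2, g), 0.75, tolerance = 1e-6)
  # cap enforced
  st17 <- stimulus_trace(rep(0, 17), g)
  expect_error(enumerate_expected_spikes(p1, st17, g, n_steps = 17), "cap")
})

test_that("spontaneous rate is non-decreasing in the inhibition constant", {
  g <- sim_grid(20)
  k2_grid <- c(0.05, 0.2, 0.5, 1)
  rates <- vapply(seq_along(k2_grid), function(i) {
    p <- sensor_params(0.04, k3 = 4, s0 = 4, k2 = k2_grid[i])
    ses <- simulate_session(p, g,
      n_sweeps = 22, seed = 11, stimulus = FALSE, n_chains = 40
    )
    mean(sweep_counts(ses)$n)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})
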