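test_that("spike phases follow theta = t/T with 1-based cycle indices", {
  ph <- spike_phases(c(0.0125, 0.05), period = 0.05)
  expect_equal(ph$fraction[1], 0.25) # quarter period
  expect_equal(ph$theta[1], pi / 2)
  expect_equal(ph$interval_index[1], 1L)
  # t = T wraps to phase 0, second cycle
  expect_equal(ph$theta[2], 0)
  expect_equal(ph$interval_index[2], 2L)
  expect_error(spike_phases(-0.01, period = 0.05), "onset")
  expect_error(spike_phases(0.1, period = 0), "> 0")
})

test_that("vector strength matches direct evaluation and its bounds", {
  expect_equal(vector_strength(rep(1.3, 5)), 1)
  expect_equal(vector_strength(c(0, pi / 2, pi, 3 * pi / 2)), 0)
  expect_equal(vector_strength(c(0, pi / 2)), sqrt(2) / 2)
  expect_error(vector_strength(numeric(0)), "empty")
})

test_that("vector strength is rotation invariant and bounded on random sets", {
  withr::with_seed(5, {
    for (i in 1:25) {
      th <- runif(sample(1:40, 1), 0, 2 * pi)
      vs <- vector_strength(th)
      expect_true(vs >= 0 && vs <= 1)
      rot <- runif(1, 0, 2 * pi)
      expect_equal(vector_strength(th + rot), vs, tolerance = 1e-12)
      # gain never exceeds count
      expect_lte(response_gain(length(th), vs), length(th))
    }
  })
})

test_that("circular variance round-trips with vector strength", {
  vs <- c(1e-6, 0.1, 0.5, 0.9, 1)
  expect_equal(exp(-circular_variance(vs) / 2), vs, tolerance = 1e-12)
  expect_equal(circular_variance(0), Inf)
})

test_that("phase quantiles equal a brute-force sort-and-interpolate oracle", {
  # evenly spaced grid
  th9 <- seq(-1, 1, length.out = 9)
  q <- phase_quantiles(th9)
  expect_equal(unname(q), brute_quantile(th9, c(0.1, 0.5, 0.9)))
  # single spike: all quantiles collapse onto it
  expect_equal(unname(phase_quantiles(0.4)), rep(0.4, 3))
  # symmetric set: median 0
  expect_equal(unname(phase_quantiles(c(-0.5, -0.2, 0, 0.2, 0.5))[2]), 0)
  # random sets, including wraparound near 2*pi
  withr::with_seed(9, {
    for (i in 1:30) {
      th <- runif(sample(2:50, 1), -0.8, 0.8)
      expect_equal(
        unname(phase_quantiles(th)),
        brute_quantile(th, c(0.1, 0.5, 0.9)),
        tolerance = 1e-12
      )
      shifted <- (th + 2 * pi) %% (2 * pi) # same angles, raw storage
      expect_equal(
        unname(phase_quantiles(shifted)),
        brute_quantile(th, c(0.1, 0.5, 0.9)),
        tolerance = 1e-12
      )
    }
  })
})

test_that("per-interval summaries track adaptation and inhibition", {
  g <- sim_grid(20)
  # nonadapting sensor: counts stable across cycles
  ns <- simulate_session(preset_sensor("nonadapting"), g,
    n_sweeps = 12, seed = 31, n_chains = 30
  )
  s1 <- per_interval_summary(ns)
  expect_equal(nrow(s1), 20)
  expect_lt(abs(mean(s1$n_mean[19:20]) / mean(s1$n_mean[1:2]) - 1), 0.15)
  expect_true(all(s1$gain <= s1$n_mean + 1e-12, na.rm = TRUE))
  expect_true(all(s1$width >= 0 & s1$width <= 2 * pi, na.rm = TRUE))
  # adapting sensor: pronounced decline in per-cycle counts
  as <- simulate_session(preset_sensor("adapting"), g,
    n_sweeps = 12, seed = 32, n_chains = 30
  )
  s2 <- per_interval_summary(as)
  expect_lt(mean(s2$n_mean[19:20]), 0.5 * mean(s2$n_mean[1:2]))
  # zero-spike cycles reported missing, not zero-imputed
  empty <- per_interval_summary(as[as$interval_index %in% 1 | is.na(as$interval_index), ],
    frequency = 20, n_intervals = 3
  )
  expect_true(all(is.na(empty$q50[empty$n == 0])))
})

test_that("strong inhibition narrows the pooled response interval", {
  g <- sim_grid(20)
  p <- preset_sensor("adapting")
  k2 <- calibrate_inhibition(p, g, 0.1)
  off <- simulate_session(p, g, n_sweeps = 12, seed = 41, n_chains = 60)
  on <- simulate_session(sensor_params(p$k1, p$k3, p$s0, k2 = k2), g,
    n_sweeps = 12, seed = 42, n_chains = 60
  )
  width_of <- function(ses) {
    th <- 2 * pi * ((ses$stim_time[ses$evoked & !ses$burn_in] * 20) %% 1)
    q <- phase_quantiles(th, center = pi / 2)
    q[[3]] - q[[1]]
  }
  expect_lt(width_of(on), width_of(off))
})

test_that("PSTH bins partition the sweep and integrate back to the count", {
  times <- c(0.01, 0.02, 0.26, 0.9, 1.49)
  tb <- psth(times, bin_width = 0.05, n_sweeps = 4, t_max = 1.5)
  expect_equal(sum(tb$width), 1.5)
  expect_equal(sum(tb$rate * tb$width) * 4, length(times))
  expect_true(all(tb$rate >= 0))
  # uniform train: flat within sampling error
  withr::with_seed(2, {
    u <- sort(runif(6000, 0, 1.5))
    tbu <- psth(u, bin_width = 0.25, n_sweeps = 1, t_max = 1.5)
    expect_lt(max(abs(tbu$n - 1000)) / 1000, 0.12)
  })
})

test_that("interspike intervals are plain sorted differences", {
  expect_equal(isi(c(0, 0.010, 0.025)), c(0.010, 0.015))
  expect_length(isi(0.3), 0)
  expect_error(isi(c(0.2, 0.1)), "sorted")
  merged <- sort(c(c(0, 0.02), c(0.01, 0.03)))
  expect_equal(isi(merged), rep(0.01, 3))
})
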