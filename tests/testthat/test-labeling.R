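make_toy_epochs <- function() {
  tibble::tribble(
    ~cell_id, ~kind, ~start_s, ~end_s,
    "c1", "stimulus", 1, 2,
    "c1", "stimulus", 4, 5,
    "c1", "swim", 0.5, 1.5,
    "c1", "swim", 3, 3.2
  )
}

test_that("a three-spike toy recording labels exactly as hand enumeration", {
  # spike 1: in stimulus [1,2) and in swim [0.5,1.5) -> evoked, CD ON
  # spike 2: outside stimulus, in swim [3,3.2) -> spontaneous, CD ON
  # spike 3: in stimulus [4,5), outside swims -> evoked, CD OFF
  sp <- tibble::tibble(cell_id = "c1", time_s = c(1.2, 3.1, 4.6))
  lab <- label_spikes(sp, make_toy_epochs(), frequency = 10)
  expect_equal(lab$evoked, c(TRUE, FALSE, TRUE))
  expect_equal(lab$cd_on, c(TRUE, TRUE, FALSE))
  expect_equal(lab$stim_time, c(0.2, NA, 0.6))
  expect_equal(lab$interval_index, c(3L, NA, 7L)) # 0.1-s cycles, 1-based
})

test_that("epoch boundaries are half-open [start, end)", {
  sp <- tibble::tibble(cell_id = "c1", time_s = c(1, 2, 1.5))
  lab <- label_spikes(sp, make_toy_epochs(), frequency = 10)
  expect_equal(lab$evoked, c(TRUE, FALSE, TRUE))
  expect_equal(lab$cd_on, c(TRUE, FALSE, FALSE)) # 1.5 is the swim's end
})

test_that("overlapping epochs of the same kind are rejected", {
  bad <- tibble::tibble(
    cell_id = "c1", kind = "stimulus", start_s = c(0, 0.5), end_s = c(1, 1.5)
  )
  expect_error(label_spikes(c(0.2), bad, 10), "overlapping")
})

test_that("labeling is a partition of the spike set", {
  withr::with_seed(12, {
    sp <- tibble::tibble(cell_id = "c1", time_s = sort(runif(300, 0, 6)))
    lab <- label_spikes(sp, make_toy_epochs(), frequency = 10)
    tab <- table(lab$evoked, lab$cd_on)
    expect_equal(sum(tab), 300)
    expect_equal(sum(lab$evoked) + sum(!lab$evoked), 300)
  })
})

test_that("activity ratios use exposure-time rates", {
  # spontaneous: 10 spikes / 2 s OFF vs 3 spikes / 1 s ON -> r_s = 0.6
  epochs <- tibble::tibble(
    cell_id = "c1",
    kind = c("swim", "stimulus"),
    start_s = c(0, 3),
    end_s = c(1, 4)
  )
  sp <- tibble::tibble(
    cell_id = "c1",
    time_s = c(seq(0.05, 0.95, length.out = 3),   # spontaneous CD ON
               seq(2.05, 2.95, length.out = 5),   # spontaneous CD OFF
               seq(1.05, 1.95, length.out = 5),   # spontaneous CD OFF
               seq(3.05, 3.95, length.out = 4))   # evoked CD OFF
  )
  lab <- label_spikes(sp, epochs, frequency = 10)
  ar <- activity_ratios(lab, epochs, total_duration = 4)
  expect_equal(ar$r_s, 0.6)
  expect_equal(ar$exposure_sp_off, 2)
  expect_equal(ar$n_ev_off, 4)
})

test_that("ratios are invariant to uniform time rescaling", {
  epochs <- tibble::tibble(
    cell_id = "c1",
    kind = c("swim", "swim", "stimulus"),
    start_s = c(0.2, 2.1, 1),
    end_s = c(0.7, 2.4, 2)
  )
  withr::with_seed(3, {
    sp <- tibble::tibble(cell_id = "c1", time_s = sort(runif(400, 0, 3)))
  })
  scale_tbl <- function(tbl, f) {
    tbl$start_s <- tbl$start_s * f
    tbl$end_s <- tbl$end_s * f
    tbl
  }
  a <- activity_ratios(label_spikes(sp, epochs, 10), epochs, total_duration = 3)
  sp2 <- sp
  sp2$time_s <- sp2$time_s * 7
  ep2 <- scale_tbl(epochs, 7)
  b <- activity_ratios(label_spikes(sp2, ep2, 10 / 7), ep2, total_duration = 21)
  expect_equal(a$r_s, b$r_s, tolerance = 1e-12)
  expect_equal(a$r_e, b$r_e, tolerance = 1e-12)
})

test_that("adaptation indices report both orientations", {
  ai <- adaptation_index(c(10, 8, 5, 4, 3, 3))
  expect_equal(ai$first_last, 3) # (9)/(3)
  expect_equal(ai$last_first, 1 / 3)
  expect_equal(adaptation_index(rep(4, 6))$first_last, 1)
  expect_error(adaptation_index(c(1, 2, 3)), "at least 4")
  flat <- adaptation_index(c(2, 2, 0, 0))
  expect_true(is.na(flat$first_last))
})
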