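test_that("well-separated blobs are recovered exactly (exhaustive oracle)", {
  withr::with_seed(77, {
    centers <- rbind(c(0.2, 0.2), c(0.9, 0.9), c(0.15, 0.95))
    xy <- do.call(rbind, lapply(1:3, function(i) {
      sweep(matrix(rnorm(6, 0, 0.02), 3), 2, centers[i, ], "+")
    }))
    ratios <- tibble::tibble(r_s = xy[, 1], r_e = xy[, 2])
    cl <- cluster_response_types(ratios, k = 3, seed = 1)
    found_sig <- partition_signature(cl$assignments$group)
    xs <- scale(as.matrix(ratios))
    expect_equal(found_sig, best_kmeans_partition(xs, 3))
  })
})

test_that("degenerate identical points are rejected informatively", {
  same <- tibble::tibble(r_s = rep(0.5, 6), r_e = rep(0.5, 6))
  expect_error(cluster_response_types(same), "degenerate")
  expect_error(
    cluster_response_types(tibble::tibble(r_s = 0.1, r_e = 0.2)),
    "fewer points"
  )
})

test_that("groups are relabeled canonically by ascending adaptation", {
  withr::with_seed(8, {
    ratios <- tibble::tibble(
      r_s = c(rnorm(5, 0.2, 0.02), rnorm(5, 0.85, 0.02), rnorm(5, 0.2, 0.02)),
      r_e = c(rnorm(5, 0.2, 0.02), rnorm(5, 0.85, 0.02), rnorm(5, 0.95, 0.02)),
      adaptation = c(rnorm(5, 1, 0.05), rnorm(5, 2, 0.1), rnorm(5, 6, 0.3)),
      planted = rep(1:3, each = 5)
    )
    cl <- cluster_response_types(ratios, seed = 2)
    expect_equal(cl$assignments$group, ratios$planted)
    # group 3 diverges: r_e >> r_s, so delta inhibition is strongly negative
    expect_lt(tidy(cl)$delta_inhibition[3], -0.5)
    expect_lt(abs(tidy(cl)$delta_inhibition[1]), 0.1)
  })
})

test_that("clustering recovers planted labels on noisy synthetic ratios", {
  # separation >= 4x within-group SD
  withr::with_seed(21, {
    n <- 20
    centers <- rbind(c(0.2, 0.2), c(0.8, 0.8), c(0.2, 0.9))
    truth <- rep(1:3, each = n)
    xy <- do.call(rbind, lapply(1:3, function(i) {
      sweep(matrix(rnorm(2 * n, 0, 0.035), n), 2, centers[i, ], "+")
    }))
    cl <- cluster_response_types(
      tibble::tibble(r_s = xy[, 1], r_e = xy[, 2]),
      seed = 3
    )
    expect_gte(label_agreement(truth, cl$assignments$group), 0.95)
  })
})

test_that("interaction regression recovers a planted coefficient", {
  gen <- function(beta, n = 50, sigma = 0.05, seed = 1) {
    withr::with_seed(seed, {
      tibble::tibble(
        r_s = runif(n, 0.1, 1),
        adaptation = runif(n, 0.2, 1),
        r_e = beta * r_s * adaptation + rnorm(n, 0, sigma)
      )
    })
  }
  fit <- interaction_regression(gen(0.6, seed = 4))
  td <- tidy(fit)
  row <- td[td$term == "r_s:adaptation", ]
  expect_true(row$conf_low <= 0.6 && 0.6 <= row$conf_high)
  # mean estimate over replicates within 10% of truth
  est <- vapply(1:60, function(s) {
    td <- tidy(interaction_regression(gen(0.6, seed = s)))
    td$estimate[td$term == "r_s:adaptation"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.6) / 0.6, 0.1)
})

test_that("null data produce no spurious interaction", {
  withr::with_seed(10, {
    null <- tibble::tibble(
      r_s = runif(40, 0.1, 1),
      adaptation = runif(40, 0.2, 1),
      r_e = 0.4 * r_s + rnorm(40, 0, 0.03)
    )
  })
  td <- tidy(interaction_regression(null))
  row <- td[td$term == "r_s:adaptation", ]
  expect_true(row$conf_low <= 0 && 0 <= row$conf_high)
  # pure noise: nothing significant
  withr::with_seed(11, {
    noise <- tibble::tibble(
      r_s = runif(40, 0.4, 0.6),
      adaptation = runif(40, 0.4, 0.6),
      r_e = rnorm(40, 0, 1)
    )
  })
  tn <- tidy(interaction_regression(noise))
  expect_true(all(tn$p_value > 0.05))
  expect_error(interaction_regression(null[1:5, ]), "at least 10")
})
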