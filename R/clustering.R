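#' Cluster cells into response types by their inhibition ratios
#'
#' k-means clustering of units (cells, or cell-by-frequency records) in
#' `(R_S, R_E)` space, the procedure that separates the three observed
#' lateral-line response types: two groups with matched spontaneous and
#' evoked inhibition (`R_E = R_S`) differing in inhibition strength, and a
#' third, strongly adapting group whose evoked rates escape inhibition
#' (`R_E >> R_S`). Ratios are standardized to unit variance before
#' clustering, and multiple random restarts with a fixed seed make the
#' result reproducible. When an `adaptation` column (First/Last response)
#' is supplied, groups are relabeled canonically by ascending mean
#' adaptation so that group 1 is always the weakest-adapting.
#'
#' @param ratios A tibble with columns `r_s`, `r_e`, optionally
#'   `adaptation` and identifier columns (kept in the output).
#' @param k Number of clusters (default 3).
#' @param seed Integer seed for the restarts.
#' @param nstart Number of k-means restarts (default 50).
#' @return An object of class `response_clusters`: a list with
#'   `assignments` (input tibble plus `group`), `centers` (tibble of
#'   per-group centroids, sizes and `delta_inhibition = r_s - r_e`), `k`,
#'   and the underlying `stats::kmeans` fit.
#' @seealso [tidy.response_clusters()], [autoplot.response_clusters()]
#' @export
cluster_response_types <- function(ratios, k = 3, seed = NULL, nstart = 50) {
  ratios <- as_tibble(ratios)
  stopifnot(all(c("r_s", "r_e") %in% names(ratios)))
  if (nrow(ratios) < k) abort("fewer points than clusters")
  x <- as.matrix(ratios[, c("r_s", "r_e")])
  sds <- apply(x, 2, sd)
  if (any(sds == 0) || nrow(unique(x)) < k) {
    abort("degenerate input: fewer than `k` distinct (r_s, r_e) points")
  }
  xs <- scale(x, center = TRUE, scale = sds)
  fit <- withr::with_seed(
    seed %||% 1L,
    stats::kmeans(xs, centers = k, nstart = nstart)
  )
  groups <- fit$cluster
  # canonical order: ascending adaptation if available, else ascending r_e
  key <- if ("adaptation" %in% names(ratios)) {
    tapply(ratios$adaptation, groups, mean)
  } else {
    tapply(ratios$r_e, groups, mean)
  }
  relabel <- match(seq_len(k), order(key))
  groups <- relabel[groups]
  out <- ratios
  out$group <- groups
  centers <- out |>
    group_by(.data$group) |>
    summarise(
      size = dplyr::n(),
      r_s = mean(.data$r_s),
      r_e = mean(.data$r_e),
      delta_inhibition = mean(.data$r_s - .data$r_e),
      .groups = "drop"
    )
  structure(
    list(assignments = out, centers = centers, k = k, fit = fit),
    class = "response_clusters"
  )
}

#' @export
print.response_clusters <- function(x, ...) {
  cat(sprintf("<response_clusters> k = %d, n = %d\n", x$k, nrow(x$assignments)))
  print(x$centers)
  invisible(x)
}

#' @rdname cluster_response_types
#' @param x A `response_clusters` object.
#' @param ... Unused.
#' @method tidy response_clusters
#' @export
tidy.response_clusters <- function(x, ...) {
  x$centers
}

#' @rdname cluster_response_types
#' @method glance response_clusters
#' @export
glance.response_clusters <- function(x, ...) {
  tibble(
    k = x$k,
    n = nrow(x$assignments),
    tot_withinss = x$fit$tot.withinss,
    betweenss = x$fit$betweenss,
    prop_between = x$fit$betweenss / x$fit$totss
  )
}

#' Interaction regression of evoked on spontaneous inhibition
#'
#' Ordinary least squares of `r_e` on `r_s`, adaptation (Last/First
#' response) and their interaction, with the intercept forced through
#' zero so approximate 95% confidence intervals of the predictors can be
#' compared with zero. In the heterogeneous-sensor analysis, variation in
#' evoked inhibition is explained by the `r_s x adaptation` interaction
#' alone: inhibition transfers to evoked rates in proportion to how little
#' the unit adapts. (The original analysis nested this structure in a
#' mixed model with random effects of individual and frequency; this
#' fixed-effects simplification is deliberate.)
#'
#' @param ratios A tibble with columns `r_e`, `r_s`, `adaptation`
#'   (Last/First).
#' @param min_n Minimum number of units required (default 10).
#' @return An object of class `cd_regression` wrapping the `lm` fit.
#' @seealso [tidy.cd_regression()], [glance.cd_regression()]
#' @export
interaction_regression <- function(ratios, min_n = 10) {
  ratios <- as_tibble(ratios)
  stopifnot(all(c("r_e", "r_s", "adaptation") %in% names(ratios)))
  if (nrow(ratios) < min_n) {
    abort(sprintf("need at least %d units", min_n))
  }
  fit <- lm(r_e ~ 0 + r_s + adaptation + r_s:adaptation, data = ratios)
  if (anyNA(coef(fit)) || fit$rank < 3) {
    abort("collinear design: interaction model is rank deficient")
  }
  structure(list(fit = fit, n = nrow(ratios)), class = "cd_regression")
}

#' @export
print.cd_regression <- function(x, ...) {
  cat(sprintf("<cd_regression> n = %d\n", x$n))
  print(tidy(x))
  invisible(x)
}

#' @rdname interaction_regression
#' @param x A `cd_regression` object.
#' @param conf_level Confidence level for the intervals.
#' @param ... Unused.
#' @method tidy cd_regression
#' @export
tidy.cd_regression <- function(x, conf_level = 0.95, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- confint(x$fit, level = conf_level)
  tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p_value = sm[, "Pr(>|t|)"],
    conf_low = ci[, 1],
    conf_high = ci[, 2]
  )
}

#' @rdname interaction_regression
#' @method glance cd_regression
#' @export
glance.cd_regression <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(
    r_squared = sm$r.squared,
    sigma = sm$sigma,
    df_residual = x$fit$df.residual,
    n = x$n
  )
}
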