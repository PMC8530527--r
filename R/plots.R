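#' Plot a per-interval response summary
#'
#' Four-panel view of evoked responses over the stimulus period: mean
#' spike count, phase quantiles (response interval), vector strength and
#' gain per stimulus cycle, split by corollary-discharge state.
#'
#' @param summary A [per_interval_summary()] tibble.
#' @return A ggplot object.
#' @export
plot_interval_summary <- function(summary) {
  long <- dplyr::bind_rows(
    dplyr::transmute(summary,
      .data$interval_index, .data$cd_state,
      metric = "count", value = .data$n_mean
    ),
    dplyr::transmute(summary,
      .data$interval_index, .data$cd_state,
      metric = "q10", value = .data$q10
    ),
    dplyr::transmute(summary,
      .data$interval_index, .data$cd_state,
      metric = "q50", value = .data$q50
    ),
    dplyr::transmute(summary,
      .data$interval_index, .data$cd_state,
      metric = "q90", value = .data$q90
    ),
    dplyr::transmute(summary,
      .data$interval_index, .data$cd_state,
      metric = "vs", value = .data$vs
    ),
    dplyr::transmute(summary,
      .data$interval_index, .data$cd_state,
      metric = "gain", value = .data$gain
    )
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$interval_index, .data$value, colour = .data$cd_state)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "stimulus interval", y = NULL, colour = "CD",
      title = "Evoked response over the stimulus period"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a peristimulus time histogram
#'
#' @param psth_tbl A [psth()] tibble.
#' @return A ggplot object.
#' @export
plot_psth <- function(psth_tbl) {
  ggplot2::ggplot(psth_tbl, ggplot2::aes(.data$t_mid, .data$rate)) +
    ggplot2::geom_col(width = psth_tbl$width, fill = "grey30") +
    ggplot2::labs(x = "time (s)", y = "rate (spikes/s)") +
    ggplot2::theme_minimal()
}

#' @rdname cluster_response_types
#' @param object A `response_clusters` object.
#' @method autoplot response_clusters
#' @export
autoplot.response_clusters <- function(object, ...) {
  ggplot2::ggplot(
    object$assignments,
    ggplot2::aes(.data$r_s, .data$r_e, colour = factor(.data$group))
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    ggplot2::geom_point() +
    ggplot2::geom_point(
      data = object$centers, shape = 4, size = 4, stroke = 1.5
    ) +
    ggplot2::labs(
      x = expression(R[S]), y = expression(R[E]), colour = "group"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname aggregate_isi
#' @param object An `isi_result` object.
#' @param ... Unused.
#' @method autoplot isi_result
#' @export
autoplot.isi_result <- function(object, ...) {
  dd <- object$density
  dd$periods <- dd$mid / object$period
  ggplot2::ggplot(dd, ggplot2::aes(.data$periods, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = 1:5, linetype = 3, colour = "grey50"
    ) +
    ggplot2::facet_wrap(~level, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "ISI (stimulus periods)", y = "density",
      title = "Population ISI structure by inhibition level"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a swim-normalized time course
#'
#' @param tc A [swim_normalized_timecourse()] tibble.
#' @param quantity Column to plot (default `"mean_count"`, or `"rate"` for
#'   spontaneous time courses).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc, quantity = "mean_count") {
  ggplot2::ggplot(tc, ggplot2::aes(.data$u_mid, .data[[quantity]])) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "relative time (swim = [0, 1], post-swim = (1, 2])",
      y = quantity
    ) +
    ggplot2::theme_minimal()
}
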