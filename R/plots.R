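# ggplot2 visualizations of the main result types.

#' Plot per-well temporal profiles
#'
#' @param features Tibble from [well_features()] / [plate_features()] (or the
#'   merged curves of a pipeline run).
#' @param y Column to plot (default `delta_confluence`).
#' @return A ggplot: one line per well over time.
#' @export
plot_profiles <- function(features, y = "delta_confluence") {
  ggplot2::ggplot(features, ggplot2::aes(x = .data$time_h, y = .data[[y]],
                                         group = .data$well, color = .data$well)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time after treatment (h)", y = y) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = if (dplyr::n_distinct(features$well) > 12) "none" else "right")
}

#' @export
autoplot.variability_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$V)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", color = NA) +
    ggplot2::geom_vline(xintercept = object$tau, linetype = 2, color = "firebrick") +
    ggplot2::labs(x = "resampled inter-plate variability V",
                  y = "simulations",
                  title = sprintf("null distribution (tau at the %gth percentile)",
                                  object$percentile)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.synergy_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$order), y = .data$B_S)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6,
                         ggplot2::aes(color = .data$p_value < 0.05)) +
    ggplot2::labs(x = "combination order", y = "scaled Bliss index",
                  color = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' Plot the prototypical response profiles of a mined group report
#'
#' @param report A [group_report()] computed with `raw_blocks` (e.g. the
#'   `report` element of [mine_responses()]).
#' @param nodes Optional subset of node ids (default: leaves).
#' @return A ggplot faceted by node, one line per readout block.
#' @export
plot_group_profiles <- function(report, nodes = NULL) {
  if (!"avg_dC" %in% names(report)) {
    rlang::abort("report lacks average blocks; build it via mine_responses() or group_report(raw_blocks=)")
  }
  d <- if (is.null(nodes)) dplyr::filter(report, .data$is_leaf) else
    dplyr::filter(report, .data$node %in% nodes)
  long <- d |>
    dplyr::rowwise() |>
    dplyr::reframe(node = .data$node,
                   block = rep(c("delta confluence", "delta morphology", "object count"),
                               each = length(.data$avg_dC[[1]])),
                   t = rep(seq_along(.data$avg_dC[[1]]), 3),
                   value = c(.data$avg_dC[[1]], .data$avg_dM[[1]], .data$avg_counts[[1]]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value, color = .data$block)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~node, scales = "free_y") +
    ggplot2::labs(x = "frame", y = "group-average response") +
    ggplot2::theme_minimal()
}
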