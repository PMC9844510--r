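# ggplot2 views of the standard result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one simulated trial
#'
#' Wrist angles and target over time for a single trial.
#'
#' @param trial A `bt_trial`.
#' @return A ggplot object.
#' @export
plot_trial <- function(trial) {
  stopifnot(inherits(trial, "bt_trial"))
  long <- tidyr::pivot_longer(trial$angles, -"time_s",
                              names_to = "series", values_to = "deg")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$deg,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)", y = "angle (deg)", colour = NULL,
      title = sprintf("%s | %s weighting, %s", trial$participant,
                      trial$weighting, trial$connection)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bt_trial <- function(object, ...) plot_trial(object)

#' Participant-level metric by condition
#'
#' One point per participant and condition, with a median crossbar -
#' the standard steady-state summary view.
#'
#' @param aggregated Table from [trim_and_aggregate()].
#' @param metric Metric column name (e.g. `"rms_error"`, `"rho"`,
#'   `"nal_l"`).
#' @return A ggplot object.
#' @export
plot_metric_by_condition <- function(aggregated, metric) {
  stopifnot(metric %in% names(aggregated))
  ggplot2::ggplot(aggregated,
                  ggplot2::aes(.data$weighting, .data[[metric]])) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6) +
    ggplot2::stat_summary(fun = median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$connection)) +
    ggplot2::labs(x = "cursor weighting", y = metric) +
    ggplot2::theme_minimal()
}

#' Effort imbalance versus coded cursor weighting
#'
#' Scatter of an imbalance metric against the coded weighting (left -1,
#' center 0, right +1) with a least-squares guide line per connection
#' level - the visual companion of [imbalance_slopes()].
#'
#' @param aggregated Table from [trim_and_aggregate()].
#' @param dv Imbalance column (`"nal_imb"`, `"ra_imb"`, `"cc_imb"`).
#' @return A ggplot object.
#' @export
plot_imbalance <- function(aggregated, dv) {
  stopifnot(dv %in% names(aggregated))
  d <- dplyr::mutate(aggregated,
                     weighting_code = code_weighting(.data$weighting))
  ggplot2::ggplot(d, ggplot2::aes(.data$weighting_code, .data[[dv]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$connection)) +
    ggplot2::scale_x_continuous(breaks = c(-1, 0, 1),
                                labels = c("left", "center", "right")) +
    ggplot2::labs(x = "cursor weighting (coded)",
                  y = paste(dv, "(left - right)")) +
    ggplot2::theme_minimal()
}
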