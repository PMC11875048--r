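#' Plot moving-window accuracy over a session
#'
#' Accuracy trace (trailing window over response trials) with the criterion
#' threshold and any rule switches marked.
#'
#' @param log a `session_log`.
#' @param window moving-window length.
#' @param threshold criterion line to draw.
#' @return a ggplot.
#' @export
plot_moving_accuracy <- function(log, window = 20L, threshold = 0.8) {
  acc <- moving_accuracy(log$trials, window)
  p <- ggplot2::ggplot(acc, ggplot2::aes(x = .data$trial_index,
                                         y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Trial", y = paste0("Accuracy (", window,
                                          "-trial window)")) +
    ggplot2::theme_minimal()
  if (nrow(log$shifts) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = log$shifts$trial_index + 0.5,
                                 colour = "red", alpha = 0.5)
  }
  p
}

#' @export
autoplot.session_log <- function(object, ...) {
  plot_moving_accuracy(object, ...)
}

#' Plot switch-aligned accuracy
#'
#' Mean accuracy by trial offset from the rule switch (offset 0 = first
#' trial under the new rule), split by congruency, with an SD ribbon.
#'
#' @param x a `switch_aligned_summary` (see [switch_aligned()]).
#' @return a ggplot.
#' @export
plot_switch_aligned <- function(x) {
  d <- x$by_offset_congruency
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset, y = .data$mean_accuracy,
                                  colour = .data$congruency,
                                  fill = .data$congruency)) +
    ggplot2::geom_vline(xintercept = -0.5, linetype = "dashed") +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$mean_accuracy - .data$sd_accuracy),
      ymax = pmin(1, .data$mean_accuracy + .data$sd_accuracy)),
      alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Trial offset from rule switch", y = "Accuracy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.switch_aligned_summary <- function(object, ...) {
  plot_switch_aligned(object)
}

#' Plot a peri-event lick histogram
#'
#' Lick rate per side around the alignment event (see [lick_psth()]).
#'
#' @param psth tibble from [lick_psth()].
#' @return a ggplot.
#' @export
plot_lick_psth <- function(psth) {
  ggplot2::ggplot(psth, ggplot2::aes(x = .data$bin_mid_ms / 1000,
                                     y = .data$rate_hz,
                                     fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Time from response window onset (s)",
                  y = "Lick rate (Hz)") +
    ggplot2::theme_minimal()
}
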