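#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_tile
#'   geom_step geom_point geom_errorbar labs theme_minimal facet_wrap
NULL

#' Plot a hypnogram
#'
#' State timeline as a step trace over recording time.
#'
#' @param object A [hypnogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hypnogram <- function(object, ...) {
  df <- as_tibble(object)
  df$t_min <- df$t_start_s / 60
  ggplot(df, aes(x = .data$t_min, y = .data$state, group = 1)) +
    geom_step(linewidth = 0.4) +
    labs(x = "Time (min)", y = NULL) +
    theme_minimal()
}

#' Plot a peri-event time histogram
#'
#' Mean firing rate per bin with an SEM ribbon (shading spans +/- SEM
#' across events).
#'
#' @param object A `psth` tibble (from [peri_transition_rates()] or
#'   [peri_stimulus_rates()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.psth <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$t_mid_s, y = .data$rate_hz)) +
    geom_line() +
    labs(
      x = sprintf("Time from %s (s)", attr(object, "alignment") %||% "event"),
      y = "Firing rate (Hz)"
    ) +
    theme_minimal()
  if (!all(is.na(df$sem))) {
    p <- p + geom_ribbon(
      aes(ymin = .data$rate_hz - .data$sem, ymax = .data$rate_hz + .data$sem),
      alpha = 0.25
    )
  }
  p
}

#' Plot bootstrap occupancy or transition estimates
#'
#' Occupancy results are drawn as per-state time courses with CI ribbons
#' (percent time in state per bin); transition results as per-pair point
#' ranges.
#'
#' @param object A `transition_boot` from [bootstrap_ci()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.transition_boot <- function(object, ...) {
  df <- as_tibble(object)
  if (attr(object, "statistic") == "occupancy") {
    ggplot(df, aes(x = .data$bin, y = 100 * .data$point,
                   colour = .data$state, fill = .data$state)) +
      geom_ribbon(aes(ymin = 100 * .data$lo, ymax = 100 * .data$hi),
                  alpha = 0.2, colour = NA) +
      geom_line() +
      labs(x = "Bin (relative to laser onset)", y = "Time in state (%)",
           colour = NULL, fill = NULL) +
      theme_minimal()
  } else {
    df$pair <- paste0(df$from, "→", df$to)
    ggplot(df, aes(x = .data$bin, y = .data$point)) +
      geom_errorbar(aes(ymin = .data$lo, ymax = .data$hi), width = 0.2) +
      geom_point(size = 0.8) +
      facet_wrap(~pair) +
      labs(x = "Bin (relative to laser onset)",
           y = "Transition probability") +
      theme_minimal()
  }
}

#' Plot an up-down testing session
#'
#' Filament force per trial on a log scale, filled by response.
#'
#' @param object An [updown_session()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.updown_session <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$trial, y = .data$filament_g,
                 shape = .data$withdrew)) +
    geom_line(aes(group = 1), colour = "grey60") +
    geom_point(size = 2.5) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                labels = c(`TRUE` = "withdrawal",
                                           `FALSE` = "no response")) +
    labs(x = "Trial", y = "Filament force (g)", shape = NULL) +
    theme_minimal()
}
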