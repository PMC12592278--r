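#' Plot a preprocessed trial: gaze coordinates and detected events
#'
#' Horizontal and vertical gaze position over trial time with saccade
#' intervals shaded and fixation intervals marked, the standard visual
#' check of the event detector.
#'
#' @param detection Result of [detect_gaze_events()].
#' @return A ggplot object.
#' @export
plot_gaze_trial <- function(detection) {
  s <- detection$samples
  long <- tidyr::pivot_longer(
    s[, c("t", "x", "y")], cols = c("x", "y"),
    names_to = "axis", values_to = "px")
  sac <- detection$events[detection$events$kind == "saccade", , drop = FALSE]
  fix <- detection$events[detection$events$kind == "fixation", , drop = FALSE]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$px)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$axis), na.rm = TRUE) +
    ggplot2::labs(x = "trial time (s)", y = "gaze position (px)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(sac)) {
    p <- p + ggplot2::geom_rect(
      data = sac, inherit.aes = FALSE, alpha = 0.2, fill = "firebrick",
      ggplot2::aes(xmin = .data$onset, xmax = .data$offset,
                   ymin = -Inf, ymax = Inf))
  }
  if (nrow(fix)) {
    p <- p + ggplot2::geom_rect(
      data = fix, inherit.aes = FALSE, alpha = 0.1, fill = "steelblue",
      ggplot2::aes(xmin = .data$onset, xmax = .data$offset,
                   ymin = -Inf, ymax = Inf))
  }
  p
}

#' Plot a trial's pupil trace with the BPS and SEPR windows
#'
#' @param samples Trial sample tibble with a combined `pupil` column (see
#'   [combine_eyes()]).
#' @param cfg A [pupil_config()] (for the window boundaries).
#' @return A ggplot object.
#' @export
plot_pupil_trial <- function(samples, cfg = pupil_config()) {
  windows <- tibble::tibble(
    window = c("BPS", "SEPR"),
    xmin = c(cfg$bps_window[1], cfg$sepr_window[1]),
    xmax = c(cfg$bps_window[2], cfg$sepr_window[2])
  )
  ggplot2::ggplot(samples, ggplot2::aes(x = .data$t, y = .data$pupil)) +
    ggplot2::geom_rect(data = windows, inherit.aes = FALSE, alpha = 0.15,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$window)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "trial time (s)", y = "pupil diameter (mm)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-cell RJA rates of a feature table
#'
#' Participant-level RJA likelihood (mean of per-trial flags) by group and
#' timepoint.
#'
#' @param features Per-trial feature tibble with `group` and `timepoint`.
#' @return A ggplot object.
#' @export
plot_rja_rates <- function(features) {
  agg <- features %>%
    dplyr::group_by(.data$group, .data$timepoint, .data$participant) %>%
    dplyr::summarise(rate = mean(as.numeric(.data$rja)), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$timepoint, y = .data$rate,
                                    fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.4, position = "dodge") +
    ggplot2::geom_boxplot(width = 0.15,
                          position = ggplot2::position_dodge(0.9),
                          outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "RJA likelihood", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest-style plot of a mediation result
#'
#' @param object An `rja_mediation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rja_mediation <- function(object, ...) {
  s <- object$summary[object$summary$effect != "prop_mediated", ]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$estimate, y = .data$effect)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "effect on outcome probability", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of marginal contrasts
#'
#' @param object An `rja_contrasts` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rja_contrasts <- function(object, ...) {
  ref <- if (object$family == "binomial") 1 else 0
  ggplot2::ggplot(object$contrasts,
                  ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = ref, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = if (object$family == "binomial") "odds ratio" else
      "difference", y = NULL) +
    ggplot2::theme_minimal()
}
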