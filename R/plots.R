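#' Plot a signed line profile
#'
#' Intensity of each channel along the spindle-to-astral axis; negative
#' positions are the spindle side, positive the astral side, 0 the peak of
#' the centrosome marker.
#'
#' @param object a [line_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot line_profile
#' @export
autoplot.line_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$position_um, y = .data$value,
                               colour = .data$channel)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "signed position (um)  [- spindle | astral +]",
                  y = "intensity (photons)", colour = "channel") +
    ggplot2::theme_minimal()
}

#' Plot a washout recovery time-course
#'
#' Per-timepoint mean enrichment with +/- 1 SE bars; significant
#' timepoints are filled, and the recovery onset, when present, is marked
#' by a vertical line.
#'
#' @param object a `recovery_result` from [recovery_onset()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot recovery_result
#' @export
autoplot.recovery_result <- function(object, ...) {
  tab <- dplyr::mutate(object$table, se = .data$sd / sqrt(.data$n))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$timepoint,
                                         y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.08, colour = "grey40") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white",
                                          `TRUE` = "#5e3c99")) +
    ggplot2::labs(x = "time after washout (h)",
                  y = sprintf("%s enrichment (photons)", object$channel),
                  fill = sprintf("p < %.2g vs 0 h", object$alpha)) +
    ggplot2::theme_minimal()
  if (!is.na(object$onset))
    p <- p + ggplot2::geom_vline(xintercept = object$onset,
                                 linetype = "dotted", colour = "#5e3c99")
  p
}

#' Peak-position summary across centrosomes
#'
#' Jittered signed peak positions per channel with the per-channel mean,
#' the spindle/astral split at 0 marked — the summary view of where each
#' signal peaks relative to the centrosome.
#'
#' @param quant quantification tibble from [quantify_scene()] /
#'   [quantify_timecourse()].
#' @param channels channels to show (default all but the marker).
#' @return a ggplot.
#' @export
plot_peak_positions <- function(quant,
                                channels = setdiff(unique(quant$channel),
                                                   "marker")) {
  dat <- quant[quant$channel %in% channels &
                 !is.na(quant$peak_position_um), ]
  means <- dplyr::summarise(dplyr::group_by(dat, .data$channel),
                            mean_pos = mean(.data$peak_position_um),
                            .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$channel,
                                    y = .data$peak_position_um,
                                    colour = .data$channel)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_point(data = means,
                        ggplot2::aes(y = .data$mean_pos), shape = 95,
                        size = 10, show.legend = FALSE) +
    ggplot2::labs(x = NULL,
                  y = "peak position (um)  [- spindle | astral +]") +
    ggplot2::theme_minimal()
}
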