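#' Plot a blink point-process power spectrum
#'
#' Power over the low-frequency band with the probe frequencies (sequence
#' rate, stimulus rate, first harmonic) marked.
#'
#' @param object A [fft_power()] result.
#' @param fmax Upper frequency limit of the panel (Hz).
#' @param probes Probe frequencies to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blink_spectrum <- function(object, fmax = 5,
                                    probes = c(0.267, 1.34, 2.67), ...) {
  df <- dplyr::filter(object, .data$freq_hz <= fmax)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$power)) +
    ggplot2::geom_vline(xintercept = probes, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power",
                  title = "Blink point-process spectrum") +
    ggplot2::theme_minimal()
}

#' Plot a binned blink-latency distribution
#'
#' Raw and smoothed normalized frequencies over the sequence window, with
#' tone onsets marked.
#'
#' @param object A [bin_and_smooth()] result.
#' @param soa_ms Tone interval (ms) for onset markers.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binned_distribution <- function(object, soa_ms = 750, ...) {
  onsets <- seq(0, max(object$t_lo), by = soa_ms)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$freq_raw), width = 18,
                      fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$freq_smooth), colour = "steelblue") +
    ggplot2::geom_vline(xintercept = onsets, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::labs(x = "Time in sequence (ms)", y = "Normalized blink frequency",
                  title = "Blink latency distribution") +
    ggplot2::theme_minimal()
}

#' Plot a five-Gaussian fit over its median curve
#'
#' @param object A [fit_five_gaussians()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gauss5_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$t_mid)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$freq), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$components$mean,
                        linetype = "dashed", colour = "firebrick",
                        alpha = 0.4) +
    ggplot2::labs(x = "Time in sequence (ms)", y = "Median blink frequency",
                  title = "Five-Gaussian description of the blink distribution") +
    ggplot2::theme_minimal()
}

#' Plot per-bin t statistics and significant clusters
#'
#' @param object A [cluster_permutation_test()] result.
#' @param alpha Significance level used to shade clusters.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_test <- function(object, alpha = 0.05, ...) {
  sig <- dplyr::filter(object$clusters, .data$p <= alpha)
  g <- ggplot2::ggplot(object$bins,
                       ggplot2::aes(x = .data$rel_lo_ms, y = .data$t))
  if (nrow(sig)) {
    g <- g + ggplot2::geom_rect(
      data = sig, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = -Inf, ymax = Inf),
      fill = "grey85")
  }
  g +
    ggplot2::geom_hline(yintercept = object$t_crit, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time relative to potential target onset (ms)",
                  y = "One-sample t of robust slopes",
                  title = "Peri-stimulus hazard-rate effect") +
    ggplot2::theme_minimal()
}

#' Plot a hazard table
#'
#' Probability mass, survival and hazard across potential target positions.
#'
#' @param table A [hazard()] result.
#' @return A ggplot object.
#' @export
plot_hazard <- function(table) {
  long <- tidyr::pivot_longer(table, c("f", "survival", "h"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Target position", y = NULL,
                  title = "Hazard-rate model of target probability") +
    ggplot2::theme_minimal()
}
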