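#' Plot an interferogram
#'
#' Voltage versus time for one (possibly averaged) interferogram period.
#'
#' @param object An `interferogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interferogram
#' @export
autoplot.interferogram <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t * 1e6, y = .data$volts)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (µs)", y = "voltage (V)",
                  title = sprintf("%s channel, %d shot(s)",
                                  object$channel, object$n_averaged)) +
    ggplot2::theme_minimal()
}

#' Plot a recovered spectrum
#'
#' Normalized photoacoustic response (proportional to the absorption
#' coefficient) over the optical axis, with the excitation spectrum for
#' context; masked bins are omitted.
#'
#' @param object A `recovered_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recovered_spectrum
#' @export
autoplot.recovered_spectrum <- function(object, ...) {
  s <- object$spectra[!object$spectra$masked, ]
  d <- tidyr::pivot_longer(
    dplyr::transmute(s, nu = .data$nu_optical / 1e12,
                     `normalized PA response` =
                       .data$pa_normalized / max(.data$pa_normalized),
                     `excitation (norm.)` =
                       .data$excitation / max(.data$excitation)),
    -"nu", names_to = "trace", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$nu, y = .data$value,
                                  colour = .data$trace)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "optical frequency (THz)", y = "relative amplitude",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot SNR scaling points with a fitted law
#'
#' @param points Tibble of SNR results (`value` plus `averaging_time` or
#'   `power`).
#' @param fit Optional `snr_fit` overlaid as a line.
#' @return A ggplot object.
#' @export
plot_snr_scaling <- function(points, fit = NULL) {
  xvar <- if (!is.null(fit) && fit$law == "snr_power_linear") "power" else "averaging_time"
  xlab <- if (xvar == "power") "optical power" else "averaging time (s)"
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data[[xvar]], y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = xlab, y = "SNR") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- exp(seq(log(min(points[[xvar]])), log(max(points[[xvar]])),
                  length.out = 50))
    ys <- if (fit$law == "snr_sqrt_tau") fit$A * sqrt(xs)
          else fit$intercept + fit$slope * xs
    p <- p + ggplot2::geom_line(data = tibble(x = xs, y = ys),
                                ggplot2::aes(x = .data$x, y = .data$y),
                                colour = "darkgreen")
  }
  p
}
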