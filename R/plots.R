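# ggplot2 views of the main result types. The Nyquist convention plots
# -Im(Z) against Re(Z) so capacitive arcs open upward.

#' Nyquist plot of a CNLS fit
#'
#' Data points with the fitted model curve overlaid, -Im(Z) vs Re(Z).
#'
#' @param object An `eis_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eis_fit
#' @export
autoplot.eis_fit <- function(object, ...) {
  d <- object$data
  f <- object$fitted
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z_real_ohm,
                                  y = -.data$z_imag_ohm)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_path(data = f, colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression(Re(Z) ~ "[" * Omega * "]"),
      y = expression(-Im(Z) ~ "[" * Omega * "]"),
      title = "Nyquist plot: data and CNLS fit"
    )
}

#' Bode magnitude/phase plot of spectra
#'
#' @param spectra Long spectrum table; colour encodes `day` when present.
#' @return A ggplot object (|Z| and phase, facetted).
#' @export
plot_bode <- function(spectra) {
  validate_spectrum(spectra)
  z <- complex(real = spectra$z_real_ohm, imaginary = spectra$z_imag_ohm)
  d <- dplyr::mutate(
    tibble::as_tibble(spectra),
    `|Z| [Ohm]` = Mod(z),
    `phase [deg]` = Arg(z) * 180 / pi
  ) |>
    tidyr::pivot_longer(c("|Z| [Ohm]", "phase [deg]"),
                        names_to = "panel", values_to = "value")
  aes <- if ("day" %in% names(d)) {
    ggplot2::aes(x = .data$frequency_hz, y = .data$value,
                 colour = factor(.data$day),
                 group = interaction(.data$device_id, .data$day))
  } else {
    ggplot2::aes(x = .data$frequency_hz, y = .data$value)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency [Hz]", y = NULL, colour = "day")
}

#' Barrier-growth trajectories
#'
#' |Z|(100 Hz) (and fitted Rb when present) per device over co-culture days.
#'
#' @param trajectories Output of [eis_trajectories()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories) {
  value_cols <- intersect(c("zmag100_ohm", "rb_ohm"), names(trajectories))
  d <- tidyr::pivot_longer(trajectories, dplyr::all_of(value_cols),
                           names_to = "metric", values_to = "ohm")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$ohm,
                                  group = .data$device_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "co-culture day", y = "resistance [Ohm]")
}

#' Calcium-switch summary plot
#'
#' Normalised mean +/- SD per platform across the three phases.
#'
#' @param summary Output of [platform_summary()].
#' @return A ggplot object.
#' @export
plot_switch_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$phase, y = .data$mean,
                                        group = .data$platform)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey30") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~platform) +
    ggplot2::labs(x = NULL, y = "normalised resistance [a.u.]")
}
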