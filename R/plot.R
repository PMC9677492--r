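# ggplot2 views of the result containers.

#' Plot an anisotropy map
#'
#' One swept axis gives a line plot of `chi`; two axes give a raster color
#' map (the figure-style `chi` vs `J0 x nu_d` view).
#'
#' @param object An `anisotropy_map` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.anisotropy_map <- function(object, ...) {
  axes <- names(object$config$axes)
  res <- object$results
  if (length(axes) == 1L) {
    ggplot2::ggplot(res, ggplot2::aes(.data[[axes[1]]], .data$chi)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(y = "relative anisotropy χ") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(
      res,
      ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]], fill = .data$chi)
    ) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "χ") +
      ggplot2::theme_minimal()
  }
}

#' Plot per-orientation yields on the sphere
#'
#' Cylindrical-projection view of the singlet yield over field
#' orientations, as produced by [orientation_yields()].
#'
#' @param yields Tibble with `theta`, `phi`, `phi_s` columns.
#' @return A ggplot object.
#' @export
plot_orientation_yields <- function(yields) {
  ggplot2::ggplot(
    yields,
    ggplot2::aes(.data$phi, cos(.data$theta), colour = .data$phi_s)
  ) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c(name = expression(Phi[S])) +
    ggplot2::labs(x = "azimuth (rad)", y = "cos(polar angle)") +
    ggplot2::theme_minimal()
}

#' Plot a coherence time series
#'
#' @param series Tibble from [coherence_series()].
#' @return A ggplot object.
#' @export
plot_coherence <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(.data$t, .data$coherence)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (µs)", y = expression(C[r] ~ "(bits)")) +
    ggplot2::theme_minimal()
}

#' Plot a control waveform
#'
#' @param object A [waveform_spec()].
#' @param ... Unused.
#' @return A ggplot object (step plot of the displacement).
#' @exportS3Method ggplot2::autoplot
autoplot.waveform_spec <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$t, .data$delta)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "time (µs)",
      y = "displacement Δ (Å)"
    ) +
    ggplot2::theme_minimal()
}
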