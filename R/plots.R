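#' Plot a lag curve
#'
#' Log-log plot of an MSD-type lag curve, or lin-log for a VACF-type
#' curve (which crosses zero and cannot be drawn on a log value axis).
#'
#' @param object A `hfbm_lagcurve` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hfbm_lagcurve <- function(object, ...) {
  kind <- attr(object, "kind") %||% "lag curve"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "lag (s)", y = kind)
  if (grepl("VACF", kind)) {
    p + ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::scale_x_log10()
  } else {
    p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
}

#' Plot a scaled-displacement propagator
#'
#' Density of the scaled displacement on a logarithmic density axis,
#' optionally with the standard normal and the obstructed-diffusion
#' reference densities overlaid.
#'
#' @param object A `hfbm_propagator` tibble.
#' @param reference Character vector, any of `"gaussian"`,
#'   `"obstructed"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hfbm_propagator <- function(object, reference = "gaussian", ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$density > 0, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$xi, y = .data$density)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(xi == x / sigma[x]), y = "PDF")
  grid <- seq(min(df$xi), max(df$xi), length.out = 400)
  if ("gaussian" %in% reference) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(xi = grid, density = dnorm(grid)),
      linetype = "dashed"
    )
  }
  if ("obstructed" %in% reference) {
    g <- grid[grid != 0]
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(xi = g, density = obstructed_propagator(g)),
      linetype = "dotdash"
    )
  }
  p
}

#' Histograms of local exponents and local diffusion coefficients
#'
#' Two-panel summary of a local analysis: the distribution of
#' `alpha_local` on a log density scale (exponential distributions
#' appear as straight lines) and the distribution of `d_local` in
#' log-log coordinates (power laws appear as straight lines).
#'
#' @param local A `hfbm_local` tibble from [local_series()].
#' @param bins Number of histogram bins for `alpha_local`.
#' @return A ggplot object (faceted).
#' @export
plot_local_distributions <- function(local, bins = 50) {
  df <- tibble::as_tibble(local)
  long <- tidyr::pivot_longer(
    df[, c("alpha_local", "d_local")],
    cols = dplyr::everything(),
    names_to = "quantity", values_to = "value"
  )
  long <- long[is.finite(long$value), , drop = FALSE]
  long$value[long$quantity == "d_local" & long$value <= 0] <- NA
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = NULL, y = "count")
}
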