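# ggplot2 visualisations mirroring the three analyses: theta-curves with the
# fitted spline, the B heatmap over TE x f, and the tractometry scatter.

#' Plot a binned anisotropy spline
#'
#' Binned means (point size by bin count) with the fitted smoothing-spline
#' curve; the magic angle is marked with a dashed line.
#'
#' @param object A `spline_aniso` from [spline_anisotropy()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spline_aniso <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$theta_mean, y = .data$value_mean)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.5) +
    ggplot2::geom_line(data = object$curve,
                       ggplot2::aes(x = .data$theta, y = .data$value),
                       colour = "#2166ac", linewidth = 1) +
    ggplot2::geom_vline(xintercept = magic_angle(), linetype = "dashed",
                        colour = "#b2182b") +
    ggplot2::labs(x = expression(theta ~ "(deg)"), y = "measure",
                  size = "voxels/bin") +
    ggplot2::theme_minimal()
}

#' Plot a simulation grid as a B heatmap
#'
#' One tile per TE x f cell, coloured by the fitted anisotropy magnitude B
#' and greyed out where the isotropic representation was selected; facets by
#' condition (rows) and measure (columns).
#'
#' @param object A `sim_grid` from [run_simulation_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sim_grid <- function(object, ...) {
  d <- dplyr::mutate(object,
                     b_shown = ifelse(.data$selected == "anisotropic",
                                      .data$b_hat, NA_real_),
                     measure = toupper(.data$measure))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$te), y = factor(.data$f),
                                  fill = .data$b_shown)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_grid(condition ~ measure) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  na.value = "grey70") +
    ggplot2::labs(x = "TE (ms)", y = "f", fill = "B") +
    ggplot2::theme_minimal()
}

#' Plot a tractometry comparison
#'
#' Segment-wise change of each measure between head orientations against the
#' change in sin^4(theta), with the origin-constrained fit line; facets by
#' measure and TE.
#'
#' @param object A `tractometry_result` from [run_tractometry()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tractometry_result <- function(object, ...) {
  long <- object$segments |>
    tidyr::pivot_longer(dplyr::all_of(paste0("d_", MEASURES)),
                        names_to = "measure", values_to = "delta",
                        names_prefix = "d_") |>
    dplyr::mutate(measure = toupper(.data$measure))
  fits <- object$summary |>
    dplyr::mutate(measure = toupper(.data$measure))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$d_sin4, y = .data$delta)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(data = fits,
                         ggplot2::aes(intercept = 0, slope = .data$b_hat),
                         colour = "#2166ac") +
    ggplot2::facet_grid(measure ~ te, scales = "free_y") +
    ggplot2::labs(x = expression(Delta ~ sin^4 * theta),
                  y = expression(Delta ~ "measure")) +
    ggplot2::theme_minimal()
}
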