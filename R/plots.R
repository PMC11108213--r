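#' Plot a spectrum trace
#'
#' @param object A `spectrum_trace`.
#' @param lines Optional line catalog to annotate (default
#'   [he_n2_lines()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectrum_trace
#' @export
autoplot.spectrum_trace <- function(object, lines = he_n2_lines(), ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$wavelength_nm,
                                    y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = "intensity (a.u.)")
  if (!is.null(lines))
    p <- p + ggplot2::geom_vline(data = lines,
                                 ggplot2::aes(xintercept = .data$wavelength_nm),
                                 linetype = "dashed", colour = "firebrick",
                                 alpha = 0.5)
  p
}

#' Plot the axial-velocity field of a jet flow solution
#'
#' @param object A `flow_field`.
#' @param ... Unused.
#' @return A ggplot raster of u_z over (z, r).
#' @method autoplot flow_field
#' @export
autoplot.flow_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z_m * 1e3,
                                       y = .data$r_m * 1e3,
                                       fill = .data$u_z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "u_z (m/s)") +
    ggplot2::labs(x = "z (mm)", y = "r (mm)")
}

#' Plot the time series of a discharge run
#'
#' @param object A `discharge_run`.
#' @param ... Unused.
#' @return A ggplot with peak/mean electron density (log scale) and mean
#'   electron temperature over time.
#' @method autoplot discharge_run
#' @export
autoplot.discharge_run <- function(object, ...) {
  df <- object$samples |>
    tidyr::pivot_longer(c("peak_ne", "mean_ne", "mean_Te"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s * 1e6, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (us)", y = NULL)
}

#' Plot snapshot profiles of electron density
#'
#' @param snapshots Snapshot tibble (`time_s`, `z_m`, `ne`).
#' @param log10_floor Densities below this are clipped for display.
#' @return A ggplot of ne(z) coloured by time.
#' @export
plot_snapshots <- function(snapshots, log10_floor = 1e12) {
  ggplot2::ggplot(snapshots,
                  ggplot2::aes(x = .data$z_m * 1e3,
                               y = pmax(.data$ne, log10_floor),
                               group = .data$time_s,
                               colour = .data$time_s * 1e6)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_viridis_c(name = "t (us)") +
    ggplot2::labs(x = "z (mm)", y = "ne (m^-3)")
}

#' Plot group means with standard-deviation error bars
#'
#' Column plot of a [compare_groups()] result, mirroring the usual
#' assay presentation (bars = group means, error bars = SD).
#'
#' @param object A `treatment_result`.
#' @param ... Unused.
#' @return A ggplot object faceted by arm and assay.
#' @method autoplot treatment_result
#' @export
autoplot.treatment_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::facet_grid(.data$assay ~ .data$arm, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
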