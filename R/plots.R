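#' T/S diagram coloured by water mass
#'
#' @param data A data frame of records.
#' @param t,s Columns (tidy-eval) holding temperature and salinity
#'   (default `sst`, `sss`).
#' @return A ggplot.
#' @export
plot_ts_diagram <- function(data, t = sst, s = sss) {
  tv <- dplyr::pull(data, {{ t }})
  sv <- dplyr::pull(data, {{ s }})
  df <- tibble::tibble(temperature = tv, salinity = sv,
                       water_mass = classify_water_mass(tv, sv))
  ggplot2::ggplot(df, ggplot2::aes(.data$salinity, .data$temperature,
                                   colour = .data$water_mass)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "Salinity", y = "Temperature (°C)",
                  colour = "Water mass") +
    ggplot2::theme_minimal()
}

#' Plot a box-model trajectory
#'
#' Facets DIC, pCO2 and the cumulative atmospheric uptake over the run.
#'
#' @param object A `box_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.box_run <- function(object, ...) {
  tr <- tidy(object) |>
    tidyr::pivot_longer(dplyr::all_of(c("dic", "pco2", "cum_uptake")),
                        names_to = "variable")
  ggplot2::ggplot(tr, ggplot2::aes(.data$day, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(c(
                          dic = "DIC (umol/kg)", pco2 = "pCO2 (uatm)",
                          cum_uptake = "Cumulative uptake (mmol C/m2)"))) +
    ggplot2::labs(x = "Day of year", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map of gridded fluxes
#'
#' @param flux_cells Output of [co2_flux()].
#' @return A ggplot of flux vs latitude/longitude, negative = uptake.
#' @export
plot_flux_map <- function(flux_cells) {
  ggplot2::ggplot(flux_cells,
                  ggplot2::aes(.data$lon, .data$lat, colour = .data$flux)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_gradient2(low = "navy", mid = "white",
                                    high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "Longitude (°E)", y = "Latitude (°N)",
                  colour = expression(F[CO2])) +
    ggplot2::theme_minimal()
}
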