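#' @title Air-sea CO2 flux with sea-ice attenuation
#' @description
#' Bulk air-sea CO2 flux per daily grid cell: quadratic wind-speed
#' dependence through the second moment of 6-hourly wind speed, Schmidt
#' number scaling to 660, linear open-water scaling by sea-ice
#' concentration with a 10% open-water floor above 90% ice cover, and
#' moist-air atmospheric pCO2. Negative flux is ocean uptake.
#' @name flux
NULL

#' Schmidt number for CO2 in seawater
#'
#' Fourth-order polynomial in temperature for CO2 in seawater of salinity
#' 35 (Wanninkhof 2014). Valid -2 to 40 degC.
#'
#' @param temperature Temperature, degC.
#' @return Dimensionless Schmidt number.
#' @export
schmidt_number <- function(temperature) {
  if (any(temperature < -2 | temperature > 40))
    stop("schmidt_number: temperature outside [-2, 40] degC", call. = FALSE)
  a <- .sc_co2_coeffs
  a[1] + a[2] * temperature + a[3] * temperature^2 +
    a[4] * temperature^3 + a[5] * temperature^4
}

#' Gas transfer velocity with sea-ice attenuation
#'
#' \eqn{k = 0.251 <U_{10}^2> (Sc/660)^{-1/2} (1 - ice_{eff}/100)} in
#' cm hr-1, where `ice_eff` is the ice concentration capped at 90% so
#' that at least 10% open water persists (leads and fine structure are
#' unresolved by the 25 km satellite ice product).
#'
#' @param u10_sq Second moment of 10 m wind speed, m2 s-2 (>= 0).
#' @param temperature Sea surface temperature, degC.
#' @param ice_pct Sea-ice concentration, percent (0-100).
#' @return Transfer velocity k in cm hr-1.
#' @export
#' @examples
#' gas_transfer_velocity(49, 0, 0)
#' gas_transfer_velocity(49, 0, 100)  # 10% of the open-water value
gas_transfer_velocity <- function(u10_sq, temperature, ice_pct = 0) {
  if (any(u10_sq < 0)) stop("u10_sq must be non-negative", call. = FALSE)
  if (any(ice_pct < 0 | ice_pct > 100))
    stop("ice_pct must lie in [0, 100]", call. = FALSE)
  ice_eff <- pmin(ice_pct, 90)
  0.251 * u10_sq * (schmidt_number(temperature) / 660)^-0.5 *
    (1 - ice_eff / 100)
}

#' Atmospheric pCO2 from dry-air mole fraction
#'
#' Corrects the dry-air CO2 mole fraction for water vapor:
#' \eqn{pCO_2^{air} = xCO_2 (P_{sl} - P_w)}.
#'
#' @param xco2 Dry-air CO2 mole fraction, ppm (>= 0).
#' @param psl Sea-level pressure, atm.
#' @param temperature Sea surface temperature, degC (for Pw).
#' @param salinity Sea surface salinity (for Pw).
#' @return Moist-air pCO2 in uatm.
#' @export
#' @examples
#' pco2_air(400, 1.0, 0, 32)
pco2_air <- function(xco2, psl, temperature, salinity) {
  if (any(xco2 < 0)) stop("xco2 must be non-negative", call. = FALSE)
  pw <- vapor_pressure(temperature, salinity, psl = psl)
  xco2 * (psl - pw)
}

#' Air-sea CO2 flux for gridded cells
#'
#' Joins daily forcing onto gridded cells by day and evaluates
#' \eqn{F = 0.24 \, K_s \, k \, (pCO_2^{sea} - pCO_2^{air})} in
#' mmol m-2 d-1. The factor 0.24 converts
#' (cm hr-1)(mol L-1 atm-1)(uatm): 0.01 m/cm x 24 hr/d x 1000 L/m3 x
#' 1e-6 atm/uatm x 1000 mmol/mol = 0.24. Negative flux is uptake by the
#' ocean.
#'
#' @param cells Gridded cells ([grid_daily()]) with `day`, `mean_sst`,
#'   `mean_sss`, `mean_pco2`.
#' @param forcing Daily forcing with `day`, `u10_sq`, `ice_pct`, `psl`,
#'   `xco2`.
#' @return `cells` with `k`, `ks`, `pco2_air`, `dpco2`, `flux` appended.
#' @export
co2_flux <- function(cells, forcing) {
  need <- c("day", "u10_sq", "ice_pct", "psl", "xco2")
  miss <- setdiff(need, names(forcing))
  if (length(miss))
    stop("forcing is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- dplyr::inner_join(tibble::as_tibble(cells),
                           tibble::as_tibble(forcing)[need], by = "day")
  out |>
    dplyr::mutate(
      k = gas_transfer_velocity(.data$u10_sq, .data$mean_sst, .data$ice_pct),
      ks = co2_solubility(.data$mean_sst, .data$mean_sss),
      pco2_air = pco2_air(.data$xco2, .data$psl, .data$mean_sst, .data$mean_sss),
      dpco2 = .data$mean_pco2 - .data$pco2_air,
      flux = 0.24 * .data$ks * .data$k * .data$dpco2
    ) |>
    dplyr::select(-dplyr::all_of(c("u10_sq", "ice_pct", "psl", "xco2")))
}

#' Regional flux summary with ACW vs non-ACW comparison
#'
#' Summarises fluxes per region (and optionally period) for the regional
#' mean and for the ACW and non-ACW groups, with a Welch t-test between
#' the two summer water-mass groups. Significance tiers: `*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001. Groups with fewer than two members get
#' their mean reported but the test is skipped and flagged.
#'
#' @param flux_cells Output of [co2_flux()] additionally carrying `region`
#'   and `group` columns (see [label_water_masses()]), and optionally a
#'   `period` column.
#' @return A tibble with one row per region (x period): group means, SDs,
#'   counts, the Welch p-value and significance flag, and `test_skipped`.
#' @export
regional_flux_table <- function(flux_cells) {
  flux_cells <- tibble::as_tibble(flux_cells)
  if (!all(c("region", "group", "flux") %in% names(flux_cells)))
    stop("flux_cells must carry region, group and flux columns", call. = FALSE)
  grp_vars <- intersect(c("region", "period"), names(flux_cells))
  one <- function(d) {
    stat <- function(x) c(mean(x), stats::sd(x), length(x))
    acw <- d$flux[d$group == "ACW"]
    non <- d$flux[d$group == "nonACW"]
    skip <- length(acw) < 2 || length(non) < 2
    p <- if (skip) NA_real_ else stats::t.test(acw, non)$p.value
    tibble::tibble(
      mean_flux = mean(d$flux), sd_flux = stats::sd(d$flux), n = nrow(d),
      mean_acw = if (length(acw)) mean(acw) else NA_real_,
      sd_acw = stats::sd(acw), n_acw = length(acw),
      mean_nonacw = if (length(non)) mean(non) else NA_real_,
      sd_nonacw = stats::sd(non), n_nonacw = length(non),
      p_value = p,
      signif = dplyr::case_when(
        is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
        p < 0.05 ~ "*", TRUE ~ ""),
      test_skipped = skip
    )
  }
  flux_cells |>
    dplyr::filter(.data$group != "excluded") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_vars))) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}
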