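#' Thermal / non-thermal decomposition of seasonal pCO2 change
#'
#' Splits the net change of surface pCO2 relative to the under-ice spring
#' reference state into a thermal component, obtained by adjusting the
#' reference pCO2 to the observed temperature with the canonical
#' isochemical temperature sensitivity of 4.23% per degC, and a
#' non-thermal remainder (biological drawdown, ice melt dilution, gas
#' exchange):
#'
#' \deqn{\Delta pCO_2 = pCO_{2,obs} - pCO_{2,ini}}
#' \deqn{\Delta pCO_2^{T} = pCO_{2,ini}(e^{0.0423 (T_{obs} - T_{spring})} - 1)}
#' \deqn{\Delta pCO_2^{nT} = \Delta pCO_2 - \Delta pCO_2^{T}}
#'
#' The decomposition is additive by construction.
#'
#' @param pco2_obs Observed pCO2, uatm (> 0).
#' @param t_obs Observed temperature, degC.
#' @param pco2_ini Under-ice spring reference pCO2, uatm (default 538).
#' @param t_spring Under-ice spring reference temperature, degC
#'   (default -1.60).
#' @param thermal_coeff Temperature sensitivity, degC-1 (default 0.0423).
#' @return A tibble with columns `d_total`, `d_thermal`, `d_nonthermal`
#'   (uatm).
#' @export
#' @examples
#' decompose_pco2(538, -1.60)           # reference state: all zero
#' decompose_pco2(200, 6.0)
decompose_pco2 <- function(pco2_obs, t_obs, pco2_ini = 538,
                           t_spring = -1.60, thermal_coeff = 0.0423) {
  if (any(pco2_obs <= 0, na.rm = TRUE))
    stop("pco2_obs must be positive", call. = FALSE)
  if (pco2_ini <= 0) stop("pco2_ini must be positive", call. = FALSE)
  d_total <- pco2_obs - pco2_ini
  d_thermal <- pco2_ini * (exp(thermal_coeff * (t_obs - t_spring)) - 1)
  tibble::tibble(d_total = d_total, d_thermal = d_thermal,
                 d_nonthermal = d_total - d_thermal)
}

#' Append the pCO2 decomposition to gridded cells
#'
#' @param cells Gridded cells from [grid_daily()] (needs `mean_pco2` and
#'   `mean_sst`).
#' @inheritParams decompose_pco2
#' @return `cells` with `d_total`, `d_thermal`, `d_nonthermal` appended.
#' @export
decompose_cells <- function(cells, pco2_ini = 538, t_spring = -1.60,
                            thermal_coeff = 0.0423) {
  dec <- decompose_pco2(cells$mean_pco2, cells$mean_sst,
                        pco2_ini = pco2_ini, t_spring = t_spring,
                        thermal_coeff = thermal_coeff)
  dplyr::bind_cols(tibble::as_tibble(cells), dec)
}
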