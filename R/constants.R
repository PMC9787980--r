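#' Physical and chemical constants used throughout the package
#'
#' Single versioned table of every empirical coefficient the package uses:
#' carbonic acid dissociation constants (Millero 2006, seawater pH scale),
#' boric acid (Dickson 1990), water self-ionization (Millero 1995), bisulfate
#' (Dickson 1990), hydrogen fluoride (Dickson & Riley 1979), CO2 solubility
#' (Weiss 1974, both gravimetric and volumetric), the Schmidt-number
#' polynomial for CO2 in seawater (Wanninkhof 2014), the gas-transfer
#' coefficient 0.251, the saturation vapor pressure over water (Buck 1981)
#' with the salinity reduction for seawater, the thermal pCO2 coefficient
#' 0.0423 per degree C (Takahashi), and the Redfield C:N:P ratio 106:16:1.
#'
#' @return A tibble with columns `name`, `value`, `unit`, `source`.
#' @export
#' @examples
#' chukchi_constants()
chukchi_constants <- function() {
  tibble::tribble(
    ~name, ~value, ~unit, ~source,
    "gas_transfer_coeff", 0.251, "cm hr-1 (m2 s-2)-1", "Wanninkhof 2014",
    "schmidt_ref", 660, "dimensionless", "CO2 in seawater at 20 degC",
    "flux_unit_factor", 0.24, "(mmol m-2 d-1) per (cm hr-1 mol L-1 atm-1 uatm)", "dimensional analysis",
    "thermal_pco2_coeff", 0.0423, "degC-1", "Takahashi et al. 1993",
    "redfield_c_n", 106 / 16, "mol C / mol N", "Redfield 106:16:1",
    "redfield_c_p", 106, "mol C / mol P", "Redfield 106:16:1",
    "ice_open_water_floor", 10, "% open water when ice > 90%", "Takahashi et al. 2009",
    "pco2_ini_default", 538, "uatm", "under-ice spring reference",
    "t_spring_default", -1.60, "degC", "under-ice spring reference",
    "s0_default", 32.1, "psu", "under-ice spring reference salinity",
    "dic_s0_default", 60, "umol kg-1", "meltwater mixing-line DIC intercept",
    "ta_s0_default", 106, "umol kg-1", "meltwater mixing-line TA intercept",
    "meltwater_s", 5, "psu", "sea-ice meltwater endmember",
    "meltwater_dic", 400, "umol kg-1", "sea-ice meltwater endmember",
    "meltwater_ta", 460, "umol kg-1", "sea-ice meltwater endmember",
    "mld_default", 25, "m", "mean mixed-layer depth",
    "boron_salinity_ratio", 0.0004157 / 35, "mol kg-1 psu-1", "Uppstrom 1974",
    "sulfate_salinity_ratio", 0.02824 / 35, "mol kg-1 psu-1", "Morris & Riley 1966",
    "fluoride_salinity_ratio", 0.00007 / 35, "mol kg-1 psu-1", "Riley 1965"
  )
}

# Schmidt-number polynomial coefficients, CO2 in seawater (S = 35),
# Sc = a0 + a1*t + a2*t^2 + a3*t^3 + a4*t^4, t in degC (Wanninkhof 2014).
.sc_co2_coeffs <- c(2116.8, -136.25, 4.7353, -0.092307, 0.0007555)
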