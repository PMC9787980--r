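#' @title Equilibrium carbonate-system computations
#' @description
#' Surface-ocean carbonate chemistry at 0 dbar: dissociation constants,
#' pCO2 from TA and DIC, the inverse, CO2 solubility, water vapor pressure
#' and seawater density. The solver works on the seawater pH scale, the
#' scale on which the Millero (2006) carbonic acid constants are published,
#' and treats the result as pCO2 directly (no fugacity correction; the
#' effect is below the uncertainty of pCO2 computed from TA and DIC).
#' @name carbonate
NULL

.check_ts <- function(temperature, salinity) {
  if (any(!is.finite(temperature)) || any(!is.finite(salinity)))
    stop("temperature and salinity must be finite", call. = FALSE)
  if (any(temperature < -2 | temperature > 35))
    stop("temperature outside supported range [-2, 35] degC", call. = FALSE)
  if (any(salinity <= 0 | salinity > 40))
    stop("salinity outside supported range (0, 40]", call. = FALSE)
  invisible(TRUE)
}

# Equilibrium constants on the seawater pH scale at 0 dbar.
# K1/K2: Millero (2006); KB: Dickson (1990b, total scale, converted);
# KW: Millero (1995); KS: Dickson (1990a, free scale); KF: Dickson &
# Riley (1979, free scale); K0: Weiss (1974), mol kg-1 atm-1.
carb_constants <- function(temperature, salinity) {
  tk <- temperature + 273.15
  lntk <- log(tk)
  s <- salinity
  sq <- sqrt(s)

  pk1 <- -126.34048 + 6320.813 / tk + 19.568224 * lntk +
    13.4191 * sq + 0.0331 * s - 5.33e-5 * s^2 +
    (-530.123 * sq - 6.103 * s) / tk - 2.06950 * sq * lntk
  pk2 <- -90.18333 + 5143.692 / tk + 14.613358 * lntk +
    21.0894 * sq + 0.1248 * s - 3.687e-4 * s^2 +
    (-772.483 * sq - 20.051 * s) / tk - 3.3336 * sq * lntk

  lnkb <- (-8966.90 - 2890.53 * sq - 77.942 * s + 1.728 * s^1.5 -
             0.0996 * s^2) / tk +
    148.0248 + 137.1942 * sq + 1.62142 * s +
    (-24.4344 - 25.085 * sq - 0.2474 * s) * lntk +
    0.053105 * sq * tk

  lnkw <- 148.9802 - 13847.26 / tk - 23.6521 * lntk +
    (118.67 / tk - 5.977 + 1.0495 * lntk) * sq - 0.01615 * s

  is <- 19.924 * s / (1000 - 1.005 * s)
  lnks <- -4276.1 / tk + 141.328 - 23.093 * lntk +
    (-13856 / tk + 324.57 - 47.986 * lntk) * sqrt(is) +
    (35474 / tk - 771.54 + 114.723 * lntk) * is -
    2698 / tk * is^1.5 + 1776 / tk * is^2 +
    log(1 - 0.001005 * s)
  lnkf <- 1590.2 / tk - 12.641 + 1.525 * sqrt(is) + log(1 - 0.001005 * s)

  ks <- exp(lnks)
  kf <- exp(lnkf)
  ts <- 0.02824 * s / 35
  tf <- 0.00007 * s / 35

  # free -> seawater scale factor; KB arrives on the total scale
  free_to_sws <- 1 + ts / ks + tf / kf
  free_to_tot <- 1 + ts / ks

  lnk0 <- -60.2409 + 93.4517 * (100 / tk) + 23.3585 * log(tk / 100) +
    s * (0.023517 - 0.023656 * (tk / 100) + 0.0047036 * (tk / 100)^2)

  list(
    k1 = 10^-pk1, k2 = 10^-pk2,
    kb = exp(lnkb) * free_to_sws / free_to_tot,
    kw = exp(lnkw),
    k0 = exp(lnk0),
    tb = 0.0004157 * s / 35
  )
}

# Residual of the alkalinity balance at proton concentration h (mol/kg,
# seawater scale): carbonate + borate + water terms minus TA.
.ta_residual <- function(h, ta, dic, k) {
  denom <- h^2 + k$k1 * h + k$k1 * k$k2
  alk_c <- dic * (k$k1 * h + 2 * k$k1 * k$k2) / denom
  alk_b <- k$tb * k$kb / (k$kb + h)
  alk_c + alk_b + k$kw / h - h - ta
}

# Safeguarded Newton iteration on [H+], bracketed over pH 4-12.
# Analytic derivative; any step leaving the bracket falls back to
# bisection. Converges to a relative tolerance of 1e-8 on h.
.solve_h <- function(ta, dic, k, reltol = 1e-8, maxit = 100L) {
  lo <- 1e-12
  hi <- 1e-4
  flo <- .ta_residual(lo, ta, dic, k)
  fhi <- .ta_residual(hi, ta, dic, k)
  if (flo * fhi > 0)
    stop(sprintf(
      "carbonate solver: no root in pH 4-12 for ta=%.1f, dic=%.1f umol/kg",
      ta * 1e6, dic * 1e6), call. = FALSE)
  h <- sqrt(lo * hi)
  for (i in seq_len(maxit)) {
    denom <- h^2 + k$k1 * h + k$k1 * k$k2
    f <- .ta_residual(h, ta, dic, k)
    # d(alk)/dh, each term analytic
    d_c <- dic * k$k1 * ((denom) - (h + 2 * k$k2) * (2 * h + k$k1)) / denom^2
    d_b <- -k$tb * k$kb / (k$kb + h)^2
    df <- d_c + d_b - k$kw / h^2 - 1
    if (f > 0) lo <- h else hi <- h  # residual decreases with h
    h_new <- h - f / df
    if (!is.finite(h_new) || h_new <= lo || h_new >= hi)
      h_new <- sqrt(lo * hi)
    if (abs(h_new - h) <= reltol * h_new) return(h_new)
    h <- h_new
  }
  stop(sprintf(
    "carbonate solver failed to converge for ta=%.1f, dic=%.1f umol/kg",
    ta * 1e6, dic * 1e6), call. = FALSE)
}

#' Surface-water pCO2 from total alkalinity and DIC
#'
#' Solves the alkalinity-DIC equilibrium (carbonate, borate and water
#' alkalinity terms) for the proton concentration with a safeguarded
#' Newton/bisection hybrid bracketed over pH 4-12, then converts the
#' aqueous CO2 concentration to a partial pressure with the Weiss (1974)
#' solubility.
#'
#' @param ta Total alkalinity, umol kg-1.
#' @param dic Dissolved inorganic carbon, umol kg-1.
#' @param temperature In-situ temperature, degC (-2 to 35).
#' @param salinity Practical salinity (0 to 40).
#' @return pCO2 in uatm (vectorised over the inputs).
#' @export
#' @examples
#' pco2_from_ta_dic(2200, 2000, temperature = 0, salinity = 32)
pco2_from_ta_dic <- function(ta, dic, temperature, salinity) {
  if (any(ta <= 0) || any(dic <= 0))
    stop("ta and dic must be positive", call. = FALSE)
  .check_ts(temperature, salinity)
  n <- max(length(ta), length(dic), length(temperature), length(salinity))
  ta <- rep_len(ta, n); dic <- rep_len(dic, n)
  temperature <- rep_len(temperature, n); salinity <- rep_len(salinity, n)
  vapply(seq_len(n), function(i) {
    k <- carb_constants(temperature[i], salinity[i])
    tam <- ta[i] * 1e-6
    dicm <- dic[i] * 1e-6
    h <- .solve_h(tam, dicm, k)
    co2aq <- dicm * h^2 / (h^2 + k$k1 * h + k$k1 * k$k2)
    co2aq / k$k0 * 1e6
  }, numeric(1))
}

#' DIC from total alkalinity and pCO2
#'
#' Inverse of [pco2_from_ta_dic()]: given TA and a CO2 partial pressure,
#' finds the DIC that closes the alkalinity balance. Used to initialise
#' and validate box-model states and to construct chemically consistent
#' synthetic surface records.
#'
#' @inheritParams pco2_from_ta_dic
#' @param pco2 CO2 partial pressure, uatm (> 0).
#' @return DIC in umol kg-1.
#' @export
#' @examples
#' dic_from_ta_pco2(2200, 400, temperature = 0, salinity = 32)
dic_from_ta_pco2 <- function(ta, pco2, temperature, salinity) {
  if (any(ta <= 0)) stop("ta must be positive", call. = FALSE)
  if (any(pco2 <= 0)) stop("pco2 must be positive", call. = FALSE)
  .check_ts(temperature, salinity)
  n <- max(length(ta), length(pco2), length(temperature), length(salinity))
  ta <- rep_len(ta, n); pco2 <- rep_len(pco2, n)
  temperature <- rep_len(temperature, n); salinity <- rep_len(salinity, n)
  vapply(seq_len(n), function(i) {
    k <- carb_constants(temperature[i], salinity[i])
    tam <- ta[i] * 1e-6
    co2aq <- k$k0 * pco2[i] * 1e-6
    # alkalinity balance with CO2* fixed: monotone in h, bracketed root
    f <- function(h) {
      co2aq * (k$k1 / h + 2 * k$k1 * k$k2 / h^2) +
        k$tb * k$kb / (k$kb + h) + k$kw / h - h - tam
    }
    h <- stats::uniroot(f, c(1e-12, 1e-3), tol = 1e-20)$root
    (co2aq * (1 + k$k1 / h + k$k1 * k$k2 / h^2)) * 1e6
  }, numeric(1))
}

#' CO2 solubility in seawater
#'
#' Weiss (1974) solubility of CO2 from moist air at 1 atm total pressure,
#' in volumetric units as used in the bulk flux formula.
#'
#' @inheritParams pco2_from_ta_dic
#' @return Solubility Ks in mol L-1 atm-1.
#' @export
#' @examples
#' co2_solubility(0, 32)
co2_solubility <- function(temperature, salinity) {
  .check_ts(temperature, salinity)
  tk <- temperature + 273.15
  lnk <- -58.0931 + 90.5069 * (100 / tk) + 22.2940 * log(tk / 100) +
    salinity * (0.027766 - 0.025888 * (tk / 100) + 0.0050578 * (tk / 100)^2)
  exp(lnk)
}

#' Water vapor pressure over seawater
#'
#' Buck (1981) saturation vapor pressure over pure water, reduced for the
#' vapor-pressure lowering by sea salt (0.0537% per unit salinity).
#'
#' @inheritParams pco2_from_ta_dic
#' @param psl Sea-level pressure in atm; the result must stay below it.
#' @return Vapor pressure Pw in atm.
#' @export
#' @examples
#' vapor_pressure(0, 32)
vapor_pressure <- function(temperature, salinity, psl = 1) {
  if (any(temperature < -2)) stop("temperature below -2 degC", call. = FALSE)
  # Buck (1981) ew1 formulation, hPa -> atm
  es_hpa <- 6.1121 * exp(17.502 * temperature / (240.97 + temperature))
  pw <- es_hpa / 1013.25 * (1 - 5.37e-4 * salinity)
  if (any(pw >= psl))
    stop("vapor pressure at or above total pressure (nonphysical)",
         call. = FALSE)
  pw
}

#' Surface seawater density
#'
#' International equation of state of seawater (EOS-80) at 0 dbar
#' (UNESCO 1983 one-atmosphere term), for practical salinity inputs.
#'
#' @inheritParams pco2_from_ta_dic
#' @return Density in kg m-3.
#' @export
#' @examples
#' sw_density(0, 32)
sw_density <- function(temperature, salinity) {
  .check_ts(temperature, salinity)
  t <- temperature
  s <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  c0 <- 4.8314e-4
  rho_w + a * s + b * s^1.5 + c0 * s^2
}
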