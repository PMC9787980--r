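Package: chukchicarb
Title: Seasonal Carbon-Cycle Analysis for the Chukchi Sea Shelf
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the seasonal carbon cycle of an Arctic
    shelf sea from underway surface records, discrete bottle chemistry and
    daily air-side forcing. Implements an equilibrium carbonate-system
    solver (total alkalinity and dissolved inorganic carbon to pCO2 with
    Millero 2006 dissociation constants), T/S water-mass classification for
    the Chukchi shelf, daily quarter-degree gridding of underway tracks,
    thermal/non-thermal decomposition of seasonal pCO2 change, air-sea CO2
    flux with sea-ice attenuation, salinity normalization of tracers with
    non-zero meltwater endmembers, net community production from
    mixed-layer nutrient and carbon drawdown with CaCO3 and gas-exchange
    corrections, and a daily mixed-layer box model comparing Redfield and
    non-Redfield C:N uptake stoichiometries. A seeded synthetic cruise-data
    generator emulates the observed two-season, two-region statistical
    structure so the full pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
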