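# chukchicarb

Seasonal carbon-cycle analysis for the Chukchi Sea shelf.

The Chukchi Sea turns from a CO2 source under spring ice into one of the
strongest CO2 sinks in the Arctic within a few weeks of ice retreat.
`chukchicarb` is an R package for scientists who want to take a season of
shelf observations — underway surface pCO2 tracks, discrete bottle
chemistry (DIC, TA, nutrients), and daily wind/ice/pressure forcing — and
quantify what drove that transition: warming, meltwater dilution,
biological drawdown, and the stoichiometry of phytoplankton carbon and
nitrogen uptake.

## What it computes

* **Carbonate system** — pCO2 from total alkalinity and DIC (and the
  inverse) with Millero (2006) dissociation constants, solved by a
  safeguarded Newton/bisection iteration; Weiss CO2 solubility, Buck
  vapor pressure, EOS-80 density.
* **Water masses** — T/S box classification (winter waters, Alaskan
  Coastal Water, Bering Summer Water, meltwaters, river water) and the
  southern/northern, ACW vs non-ACW partition.
* **Gridding** — daily 0.25° × 0.25° cell means of underway tracks.
* **pCO2 decomposition** — net seasonal change relative to the under-ice
  reference (538 µatm at −1.60 °C) split into a thermal part,
  `pCO2_ini (e^{0.0423 ΔT} − 1)`, and a non-thermal remainder.
* **Air–sea flux** — `F = 0.24 Ks k ΔpCO2` with
  `k = 0.251 <U10²> (Sc/660)^{−1/2}` and linear sea-ice attenuation with
  a 10% open-water floor above 90% ice; Welch t-tests between water-mass
  groups. Negative flux is ocean uptake.
* **NCP** — salinity-normalized (non-zero meltwater endmembers) drawdown
  of nitrate, phosphate and DIC converted to mixed-layer net community
  production, with CaCO3 and gas-exchange corrections of the carbon
  budget, C:N / C:P uptake-ratio diagnostics and an N2-fixation
  sensitivity.
* **Box model** — a daily mixed-layer DIC model whose air–sea flux feeds
  back on its own solved pCO2, comparing Redfield (C:N = 6.6) and
  non-Redfield (10.9, 12.1) uptake scenarios to quantify how much CO2
  uptake flexible stoichiometry supports.
* **Synthetic data** — a seeded generator reproducing the two-region,
  two-season statistical structure of the observations, so the entire
  pipeline runs and is testable with no external data.

## Worked example

```r
library(chukchicarb)

# the headline arithmetic: southern nitrate drawdown 10.24 uM over a
# 25 m mixed layer and a 73-day growing season
ncp_nutrient(10.24, mld = 25, dt = 73)
#> [1] 3.506849    # mmol N m-2 d-1, prints as 3.51

# full synthetic pipeline, seeded
spec   <- cruise_spec(seed = 7)       # true C:N = 6.6 by default
report <- run_pipeline(spec)

dplyr::select(report$ncp, region, d_ndic, d_nno3, ncp_dic, ncp_n, cn_uptake)
#> # A tibble: 2 × 6
#>   region   d_ndic d_nno3 ncp_dic ncp_n cn_uptake
#> 1 southern   30.1   9.08    20.1  3.11      6.45
#> 2 northern   40.7   8.04    25.4  4.10      6.19
```

The pipeline recovers the C:N uptake ratio the generator prescribed
(6.6) to within the station-noise uncertainty: `d_nno3` is the
normalized nitrate drawdown (µM), `ncp_dic` and `ncp_n` the DIC- and
nitrate-based NCP (mmol m⁻² d⁻¹), and `cn_uptake` their ratio.

```r
dplyr::select(report$scenario_comparison, region, uptake_nonredfield,
              uptake_redfield, enhancement_pct)
#> # A tibble: 2 × 4
#>   region   uptake_nonredfield uptake_redfield enhancement_pct
#> 1 southern               949.            673.            41.0
#> 2 northern               363.             99.3          266.
```

Cumulative CO2 uptake (mmol C m⁻²) over the growing window is higher in
the non-Redfield runs on identical forcing — the southern enhancement
(41%) sits right at the observed value, while the short ice-capped
northern window makes the relative northern enhancement large. From the
published cumulative totals the same arithmetic gives:

```r
scenario_compare(751, 528)
#>   enhancement_pct flexibility_share_pct
#> 1            42.2                  29.7
```

i.e. flexible phytoplankton stoichiometry supports ~30% (southern) to
~46% (northern, from `scenario_compare(343, 185)`) of the CO2 uptake.

Plot helpers: `plot_ts_diagram()` (T/S diagram coloured by water mass),
`autoplot()` on a box run (DIC, pCO2 and cumulative-uptake trajectory),
`plot_flux_map()`; `tidy()`/`glance()` give broom-style views of box
runs.

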