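---
title: "Methods: seasonal carbon-cycle analysis of an Arctic shelf sea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal carbon-cycle analysis of an Arctic shelf sea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chukchicarb)
```

`chukchicarb` implements a complete analysis chain for the seasonal carbon
cycle of the Chukchi Sea shelf: from underway surface pCO2 tracks and
discrete bottle chemistry to air–sea CO2 fluxes, net community production
(NCP) and a mixed-layer box model that quantifies how a flexible
phytoplankton C:N uptake stoichiometry enhances oceanic CO2 uptake. This
vignette documents the models, their assumptions, the tunable parameters,
the numerical choices, and what the synthetic data generator does and does
not emulate.

## The carbonate-system solver

All pCO2 values derived from bottle chemistry, and every daily step of the
box model, go through an equilibrium solver for the seawater CO2 system.
Given total alkalinity (TA) and dissolved inorganic carbon (DIC), the
solver finds the proton concentration that closes the alkalinity balance

$$TA = [HCO_3^-] + 2[CO_3^{2-}] + [B(OH)_4^-] + [OH^-] - [H^+],$$

then converts the residual aqueous CO2 to a partial pressure with the
Weiss (1974) solubility. Choices:

* **Constants.** Carbonic acid K1/K2 from Millero (2006), the set
  recommended for cold, brackish-to-oceanic shelf waters; boric acid from
  Dickson (1990); water self-ionization from Millero (1995); total boron
  from salinity (Uppström). Nutrient alkalinity terms are omitted:
  surface nitrate and phosphate alkalinity here contribute well under
  1 µmol kg⁻¹, far below the ±18 µatm uncertainty that computed pCO2
  carries anyway.
* **pH scale.** Everything is evaluated on the *seawater* scale, because
  that is the scale the Millero (2006) constants are published on; the
  boric acid constant is converted from the total scale with explicit
  sulfate and fluoride association constants. The solver's pCO2 output is
  scale-independent.
* **Root finding.** A safeguarded Newton iteration on [H⁺] with an
  analytic derivative, bracketed over pH 4–12; any Newton step leaving
  the bracket falls back to bisection of the current bracket. Relative
  tolerance 1e-8 on [H⁺]; non-convergence raises an error naming the
  inputs.
* **Fugacity.** The solver output is treated as pCO2 directly. The
  fugacity correction is ≤ 3 µatm at these temperatures — below the
  stated uncertainty of TA/DIC-derived pCO2 — and is deliberately not
  applied.
* **Verification.** The test suite compares the solver against a frozen
  125-point reference grid (TA 2100–2300, DIC 1900–2200, T −1.8 to 10 °C
  at S = 32) computed by an independently written reference solver that
  solves the full speciation system, including explicit bisulfate and
  fluoride terms, for the free proton concentration. Agreement is far
  inside 1 µatm. The TA/DIC ↔ TA/pCO2 round trip closes to better than
  0.01 µmol kg⁻¹.

Seawater density uses the EOS-80 one-atmosphere equation (inputs are
practical salinity), pinned against the published UNESCO check values.
Water vapor pressure uses Buck (1981) over pure water with the standard
0.0537% per-salinity-unit reduction for seawater.

## Water masses, regions and groups

Observations are classified from T/S into the canonical Chukchi shelf
water masses: newly-ventilated and remnant winter water (NVWW, RWW),
Alaskan Coastal Water (ACW), Bering Summer Water (BSW), early- and
late-season meltwater (ESMW, LSMW), River Water (RW) and — only when a
below-shelf depth flag is supplied — Atlantic Water (AW). Design points:

* All box inequalities are strict, exactly as defined; a sample lying
  exactly on a boundary (e.g. T = 0) is labelled `OTHER` and excluded
  from group statistics. The definition table leaves genuine T/S gaps
  (e.g. 0 < T < 3 with S > 33.6); such samples are `OTHER` too.
* RW (T > 8, S < 30) lies inside the LSMW box; RW wins, reflecting its
  treatment as the warm, river-influenced extreme of the coastal-current
  water. This is the only overlap, and an exhaustive 0.1°-resolution grid
  scan in the tests verifies no other point matches two boxes.
* For the flux statistics, records split at 69.5 °N into southern and
  northern shelf and into an ACW group (ACW + RW), a non-ACW group
  (BSW + both meltwaters), winter water, and excluded; the study domain
  is 66–74 °N.

## Gridding, decomposition and flux

Underway tracks are averaged into daily 0.25° × 0.25° cells (half-open
bins anchored at 0°, UTC day boundary) so that densely sampled patches do
not dominate regional statistics. Per-cell, the seasonal pCO2 change
relative to the under-ice spring reference (538 µatm at −1.60 °C,
configurable) decomposes into a thermal part,
$pCO_{2,ini}\,(e^{0.0423\,\Delta T} - 1)$, and a non-thermal remainder;
the decomposition is additive by construction.

The air–sea flux per cell is

$$F = 0.24\, K_s\, k\, (pCO_2^{sea} - pCO_2^{air}), \qquad
k = 0.251 \langle U_{10}^2\rangle (Sc/660)^{-1/2} (1 - ice_{eff}/100),$$

with $K_s$ the volumetric Weiss solubility, the Schmidt number from the
fourth-order seawater polynomial (Wanninkhof 2014), and
$ice_{eff} = \min(ice\%, 90)$: above 90% satellite ice cover a 10%
open-water fraction persists, representing leads unresolved by the 25 km
ice product. Negative flux is ocean uptake. The 0.24 factor is pure unit
conversion (0.01 m cm⁻¹ × 24 h d⁻¹ × 1000 L m⁻³ × 10⁻⁶ atm µatm⁻¹ ×
1000 mmol mol⁻¹). The regional summary compares ACW vs non-ACW by Welch's
t-test (group variances differ visibly, so the unequal-variance form is
the defensible default); groups with n < 2 report a mean but skip the
test with a flag.

Forcing joins cells by day. Where a single period-mean wind and pressure
is preferred over daily forcing, pass a forcing table with those means
repeated — the pipeline is agnostic.

## Salinity normalization and NCP

Tracer concentrations are projected to the under-ice spring reference
salinity S₀ along conservative mixing lines:
$nC = (C - C_{S=0})/S \times S_0 + C_{S=0}$. The meltwater endmember
(S = 5, DIC = 400, TA = 460 µmol kg⁻¹) corresponds to freshwater
intercepts of 60 (DIC) and 106 (TA) µmol kg⁻¹; nutrients use zero
intercepts because meltwater carries negligible nitrate and phosphate.
S₀ defaults to 32.1, the mean early-spring under-ice surface salinity of
the northern shelf; it is configurable because only "mean salinity under
the ice in spring" is specified, and the downstream drawdown ratios are
insensitive to it.

All seasonal deltas are spring-minus-later, so positive values are
drawdowns. NCP is then

* nitrate/phosphate-based: $\Delta nX \times MLD / \Delta t$ with
  MLD = 25 m and growing seasons of 73 d (southern) and 49 d (northern);
* DIC-based: $(\Delta nDIC \cdot \bar\rho - \Delta DIC_{CaCO_3})
  \times MLD/\Delta t - \overline{F_{CO_2}}$, where the mean flux
  (negative into the sea) removes the DIC the atmosphere added, and

$$\Delta DIC_{CaCO_3} = \tfrac12\,(\Delta nTA \cdot \rho/1000 + \Delta nNO_3^-).$$

The CaCO3 term deserves a note. The printed form of this correction is
sign- and unit-ambiguous; we pin the *nitrate-credit* convention —
biological nitrate uptake raises TA one-for-one, so the CaCO3-driven TA
change is the observed ΔnTA with the nitrate contribution credited back
before halving (standard alkalinity bookkeeping after Brewer & Goldman).
Under this convention a pure nitrate-uptake alkalinity change yields
exactly zero, and a net nTA increase diagnoses dissolution (e.g. ikaite
released from melting ice) that *adds* DIC and would otherwise mask true
production. Because no single convention we tested reproduces both
published regional CaCO3 shares, the share is exposed as a diagnostic
(`caco3_share` in `ncp_summary()`), not asserted against published
values. Where the formula's single ρ is needed, the mean of the
spring and summer surface densities is used.

The C:N uptake ratio is NCP(DIC)/NCP(N); N2 fixation can be credited to
the nitrogen side as rate × depth/1000 (the published upper bound,
3.60 nmol N L⁻¹ d⁻¹ over 25 m, adds 0.09 mmol N m⁻² d⁻¹). A
depth-integrated variant applies the same operations to station-depth
inventories; the generator produces bottom-layer samples for it.

## The mixed-layer box model

A single 25 m box integrates DIC daily over the growing window (day
136–219 southern, 167–219 northern):

$$DIC_{t+1} = DIC_t
  - \frac{F_{CO_2,t}\,\tau}{MLD\,\rho}
  - \frac{NCP_{N,t}\cdot(C{:}N)\,\tau}{MLD\,\rho}
  + \frac{TA_{t+1}-TA_t}{TA_t}\,DIC_t \;(+\, CaCO_3\ source),$$

with the flux computed from the model's *own* pCO2 (solved from TA and
DIC each day), so biological drawdown feeds back on influx. TA is
prescribed (linear between the observed spring and summer means) and
carries the meltwater dilution; density is recomputed daily from forced
SST/SSS. Design points:

* **Daily NCP forcing.** The nitrogen-drawdown time course is not
  observed; the default is a uniform daily NCP_N whose window total
  matches the regional drawdown times MLD (e.g. 10.24 µM × 25 m
  southern), with a triangular bloom-shaped alternative of identical
  total. The totals, not the shape, constrain cumulative uptake.
* **Operator order** within a step is fixed — flux, then NCP, then
  dilution — and at τ = 1 d the alternative ordering changes DIC by well
  under 0.5 µmol kg⁻¹ over a full run (asserted in the tests).
* **CaCO3 scenario.** The diagnosed dissolution DIC can be spread
  uniformly over the run as an extra source term, giving the
  with/without-correction scenario pair.
* **Budget closure.** Final minus initial DIC equals the summed step
  terms to < 1e-9 µmol kg⁻¹; cumulative uptake is exactly the negative
  time-integral of the flux series.

Comparing a non-Redfield run (C:N 10.9 southern, 12.1 northern) with a
Redfield run (6.6) on identical forcing gives the *enhancement*
$(U_{nr}-U_r)/U_r$ and the *flexibility share* $(U_{nr}-U_r)/U_{nr}$.
From the published cumulative totals these evaluate to 42%/85%
enhancement and 30%/46% share; with the synthetic forcing the southern
pair falls in the same 1.4–1.9 uptake-ratio range, while the northern
pair shows a larger *relative* enhancement because the short, ice-capped
northern window makes the absolute Redfield uptake small — a feature of
the synthetic conditions, not of the arithmetic. Reproducing the absolute
totals (751/528 and 343/185 mmol C m⁻²) requires the deposited cruise
forcing and is out of scope here; only the ratios are asserted.

## The synthetic generator

The generator exists so every stage runs and is testable offline. It
emulates:

* two regions × two seasons of surface (and bottom) bottle statistics at
  the documented means and SDs — near-freezing, salty, nutrient-rich and
  CO2-supersaturated in spring; warm, fresh and nitrate-depleted in
  summer;
* under-ice spring pCO2 of 538 ± 68 µatm, with DIC back-computed from TA
  and pCO2 through the solver so the generated chemistry is internally
  consistent;
* meltwater freshening along the exact configured mixing-line
  intercepts, so salinity normalization removes the dilution exactly (a
  deliberate idealization: with the nominal S = 5 endmember the removal
  would be approximate at the < 0.5% level);
* a prescribed true C:N uptake ratio encoded exactly in the paired
  DIC/nitrate deficits before noise, with N:P fixed at 16:1 and the
  one-for-one nitrate TA credit included, plus a configurable
  gas-exchange DIC addition consistent with the flux the pipeline will
  subtract;
* seasonal forcing: deterministic logistic ice retreat (100% → 0%,
  midpoint day 150 south / 185 north), SST ramp from freezing to the
  regional summer mean, AR(1) winds around 49 m² s⁻², ~1 atm pressure
  and ~400 ppm xCO2 with a small seasonal drawdown.

It does **not** emulate spatial circulation or advection, real
along-track autocorrelation, an ACW vs non-ACW biogeochemical contrast
(both groups share the regional statistics, so the significance machinery
of the flux table is exercised with constructed cohorts in the tests),
vertical mixing events, or NetCDF-gridded satellite products. Passing
tests therefore demonstrate correct arithmetic, internal consistency and
parameter recovery under the documented statistical structure — not skill
against real cruise data.

Parameter recovery: noise-free, the pipeline returns the prescribed C:N
exactly (machine precision). At the documented SDs with 15 stations per
region, single-seed estimates scatter by roughly ±15%, and the mean over
100 seeds is within ~3% of truth for C:N ∈ {6.6, 10, 12}; the test suite
asserts a 10% bound on that 100-seed mean.

## Problem sizes and determinism

Default test and pipeline sizes — 800 underway records per period, 15
stations per region/period, 151 forcing days, 100 recovery seeds — keep a
full run in seconds on one core while leaving every statistic stable at
the asserted tolerances. All stochastic draws sit behind a single integer
seed in `cruise_spec()`; a seeded report is bit-reproducible.

## Known limitations

* The carbonate solver targets the surface (0 dbar) configuration only:
  no pressure corrections, no pH/carbonate-ion outputs, one constants
  set. It is not a general CO2SYS replacement.
* The flux parameterization is the quadratic-wind form only; alternative
  gas-exchange formulations are out of scope.
* The CaCO3 correction's published form is ambiguous (see above); the
  pinned convention is internally consistent but its regional share
  should be read as a diagnostic.
* The box model has no entrainment, lateral advection or prognostic ice
  melt; dilution enters only through the prescribed TA trajectory.
* River/precipitation endmember variants are not implemented, but the
  normalization intercepts are configurable for users who want to emulate
  them.
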