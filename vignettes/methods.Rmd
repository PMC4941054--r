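---
title: "Methods: simulating chemical weathering by early non-vascular vegetation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating chemical weathering by early non-vascular vegetation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptoweather)
```

## The question and the modelling strategy

Before vascular plants, the land surface of the Late Ordovician (~450 Ma)
could have carried extensive lichen and bryophyte covers. These organisms
dissolve surface rock to acquire phosphorus, so their net primary
productivity (NPP) implies a chemical weathering flux; enhanced silicate
weathering in turn draws down atmospheric CO2. `cryptoweather` implements a
desk-scale version of this argument as a chain of components:

1. a **synthetic climate generator** producing monthly fields with the
   statistical structure of a paleo-GCM climatology, and a **stochastic
   weather generator** disaggregating them to hourly drivers;
2. a **trait-sampled vegetation model**: several hundred artificial species
   drawn Monte-Carlo from lichen/bryophyte trait ranges, each run through an
   hourly poikilohydric water balance and Farquhar photosynthesis with a
   carbon-concentration mechanism (CCM), with survival filtering and
   competitive aggregation per grid cell;
3. a **weathering module** converting NPP to phosphorus demand and rock
   volume, capping the flux by erosion- and runoff-based supply limits
   (the latter from the calcite equilibrium at the soil CO2 pressure), and
   feeding the phosphorus shortfall back onto NPP;
4. **reference models**: Budyko runoff, the GEM-CO2 runoff-lithology
   regression, and GEOCARB-III-style scaling of an abiotic weathering flux.

The real study forcing (monthly LMDZ fields) is not publicly deposited, so
the package generates its own synthetic world. Absolute global numbers are
therefore properties of that synthetic world; what carries over are the
**mechanisms, directions and in-paper arithmetic**: the limit structure of
weathering, the CO2 sensitivity and its saturation, the phosphorus
bookkeeping, and the stoichiometric worked examples, all of which are
exercised by the test suite.

## Synthetic climate and paleogeography

The grid is regular in longitude/latitude with exact spherical cell areas
(default 48 x 24 for experiments, 8 x 8 in unit tests). Land is thresholded
from a latitudinally biased smoothed random field so that a configurable
fraction (default 0.25) of the globe is land, concentrated in a
south-polar supercontinent with low-latitude landmasses; elevation combines
a distance-to-coast ramp (coastal lowlands, interior highlands up to
~1500 m) with smoothed noise. The `hirnantian_ice` scenario prescribes
glaciers on all land south of 30 deg S.

Monthly climate is built from analytic zonal structure plus seeded
multiplicative noise:

* temperature `28 - 42 sin^2(lat)` degC with a lapse correction over
  elevated land and a seasonal cycle (amplitude growing poleward, opposite
  phase in the two hemispheres);
* CO2 coupling imposed analytically: `dT = S log2(CO2/CO2_ref)` with
  `S = 3` degC per doubling about the 8 PAL reference, plus an extra
  quadratic cooling below the reference (the land response steepens at low
  CO2), and precipitation scaled by +2% per degC of CO2-driven warming
  (Clausius-Clapeyron-like; a warming sweep with frozen precipitation would
  dry the world unphysically);
* rainfall from a seasonally migrating equatorial belt, arid subtropics
  near +/-30 deg and mid-latitude storm tracks; snow partitioned by a
  logistic in temperature;
* shortwave from daily-mean top-of-atmosphere insolation (solar constant
  1307 W m-2, ~96% of modern) under rainfall-dependent transmission;
  longwave from a grey atmosphere; relative humidity tied to rainfall.

The weather generator maps each month to 30 days x 24 h: a sinusoidal
diurnal temperature cycle (default amplitude 8 degC, peak 14:00), a
daylight half-sine for shortwave with day length from latitude and season,
relative humidity in anti-phase to temperature (coupling damped so the
series stays in [0, 1]), and precipitation as wet events with exponential
dry gaps (mean 72 h) and durations (mean 6 h). Every hourly series is
rescaled to reproduce its monthly mean (states) or total (fluxes) exactly;
this conservation contract, bit-identical determinism given the seed, and
the physical bounds are the tested guarantees. The event statistics and the
diurnal amplitude are package choices (the original study's generator is
not published in detail); they matter mainly through the wet-hour fraction,
which sets how long thalli stay metabolically active.

## The vegetation model

Each artificial species is a parameter vector sampled uniformly
(log-uniformly for rate constants) from ranges representative of published
lichen/bryophyte physiology: Rubisco capacity `vcmax_ref` 1.5-18
umol m-2 s-1 (at 20 degC), `jmax/vcmax` 1.5-2.5, respiratory Q10 1.8-2.5,
saturated thallus CO2 diffusivity 3e-5 to 1e-3 m s-1, water storage 1-8
kg m-2, albedo 0.08-0.30, thermal optimum 5-35 degC. Two quantities are
universal physiological constraints shared by all species of a simulation:
the Rubisco-to-respiration ratio `phi_rr` (default 15; reference
respiration is `vcmax_ref / phi_rr`) and the CCM factor `eta_ccm`
(default 8, sensitivity range 2-45).

**Water.** The thallus is a single reservoir: rain, dew (on humid, mild
nights) and snowmelt fill it; evaporation is bounded by the available water
and by the equilibrium-evaporation energy bound
`s/(s+gamma) Rn / lambda` (the full heat-balance iteration of the original
scheme is reduced to this bound with a fixed aerodynamic conductance; the
0.01 m roughness length is recorded in the configuration); overflow above
the storage capacity leaves as runoff. The budget closes exactly and is
audited to 1e-9 kg m-2 per cell-year. Metabolism requires water saturation
above a threshold (default 10% - poikilohydry: dry thalli shut down),
above-freezing temperature and a snow-free surface.

**Snow.** A degree-day melt scheme with a lateral (glacier-flow) loss
proportional to the pack; cells whose projected pack exceeds 1000 kg m-2
snow-water equivalent are treated as glaciated and carry no vegetation. A
prescribed glacier mask overrides the dynamic state.

**Carbon.** Gross assimilation is the Farquhar minimum of
carboxylation- and light-limited rates at the chloroplast CO2
`Cc = eta_ccm * ci`, with the CCM's electron cost debited from the light
reactions (`J_eff = J / (1 + 0.02 (eta_ccm - 1))`). The internal CO2 `ci`
balances diffusive supply `D(saturation) * (ca - ci)` against demand; `D`
decreases with water content (wet thalli are diffusion-limited - this is
what keeps the CO2 response unsaturated far above modern concentrations)
from `dry_factor = 10` times the saturated value down to `d_co2_sat`. The
balance is solved by bisection (60 halvings, i.e. to machine precision;
the generic solver in `internal_co2()` documents a 1e-9 relative
tolerance). Kinetic constants follow Bernacchi-type Arrhenius responses
with the CO2 compensation point scaled linearly in O2. Capacities rise
Q10-like with temperature (factor 2 per 10 degC, matching the scale of the
respiratory Q10 so that the capacity-to-respiration ratio is approximately
temperature-neutral below the optimum) and are Gaussian-deactivated above
the species' `t_opt`. Respiration is `resp_ref * q10^((T-20)/10)` whenever
the thallus is active. NPP = GPP - respiration holds identically per
species, hour and aggregate.

**Annual bookkeeping and aggregation.** The forcing year repeats
identically, so the hourly integration is run for `n_hourly_years`
(default 2) years - the first spins up the reservoirs - and the final
year's per-species annual fluxes drive a literal annual loop for `n_years`
(default 50 at desk scale; the full 600-year protocol is a configuration
choice): biomass gains NPP and loses a 0.1 yr-1 turnover, disturbance
resets biomass to the seed state every `tau_d_years` (default 100), and a
species dies when its biomass falls below 1% of the seed value at an
annual checkpoint (the survival reading of "cannot maintain its biomass").
Cover is `1 - exp(-biomass/1500 g C m-2)`. Cell values are weighted means
over survivors; the weights are area shares from replicator-style
competition for space, compounding each year with annual production -
algebraically a softmax of accumulated NPP with rate
`competition_rate * n_years` (default 0.01 per g C m-2 yr-1 per year). A
literal linear weighting by accumulated NPP makes community NPP a weighted
mean that *decreases* when weak survivors are added, which contradicts the
observed rise of global NPP with initial species number; the replicator
form expresses the competitive exclusion that the trait-sampling argument
relies on (the best-adapted strategy takes over the cell), and under it
both the species-number effect and the selection property (high-CO2 runs
favour higher-capacity dominants) hold robustly.

## Weathering

Potential NPP implies a phosphorus demand
`(NPP / cp_mass_ratio) * (1 - resorption + leaching) / recycling_ratio`.
Resorption and leaching nearly compensate (both default 0.6, net factor
exactly 1). The C:P mass ratio of 350 g C per g P is the package's
calibration choice: with it, the canonical desert ecosystem (NPP 5 g C
m-2 yr-1, surface weathering 0.002 mm yr-1, rock phosphorus 1432 g m-3)
yields a recycling ratio of 5:1 exactly - the pre-vascular default.
Dividing the demand by the rock phosphorus concentration gives the
NPP-based weathering volume.

Two supply limits cap this flux cell-wise:

* **erosion**: in steady state chemical weathering cannot outpace the
  exposure of fresh rock, taken proportional to elevation with
  `k_e = 6e-8 yr-1` (0.06 mm yr-1 at 1000 m);
* **runoff**: solute export is runoff (counted from the vegetated fraction
  only) times the equilibrium calcium concentration, divided by the rock
  calcium concentration. The calcium ceiling comes from the open-system
  calcite equilibrium at the soil CO2 pressure (default 10000 ppm),
  solved from the full speciation charge balance by bisection in log
  proton activity; equilibrium constants are the standard 25 degC values
  (their temperature dependence is neglected - the tested contracts are
  the pCO2 response, including the ideal cube-root law, and agreement
  with an independent polynomial-root speciation solve to 1e-6). The
  regolith composition factor scales the calcite term (0 = no Ca-bearing
  minerals).

Realized weathering is the cell-wise minimum (tie labels with priority
npp > erosion > runoff), and where the limits bind, realized NPP is scaled
by `w_realized / w_npp` - the phosphorus feedback. Because the NPP-to-rock
conversion is globally uniform, the global fractional reductions of NPP
and weathering agree by construction. The global molar calcium
concentration of rock, 7.7e12 mol / 1.8e9 m3 ~ 4278 mol m-3, is calibrated
from the printed flux/volume pair and cross-checked against the
independent 5.5e12 mol <-> 1.3 km3 pair (agreement within 4%); the
six-class lithology mix shipped with `rock_geochem()` is a synthetic
illustrative composition.

## Reference models

`budyko_runoff()` partitions annual precipitation with the Budyko curve,
using equilibrium evaporation for potential evaporation; runoff obeys
`max(0, P - PET) <= R <= P`. `gem_co2_flux()` is linear in runoff per
lithology class; the relative class slopes (carbonates far above
silicates) are scaled by `calibrate_gem_slopes()` so a present-day
reference runoff field reproduces the configured component fluxes
(silicate 3.4e12, carbonate 2.1e12 mol Ca yr-1; the original per-class
constants are treated as a scaling reference, not reproduced).
`geocarb_abiotic()` scales those component fluxes with the standard
GEOCARB III forms - silicate `exp(0.09 dT) (1 + 0.038 dT)^0.65`, carbonate
`1 + 0.087 dT`, an abiotic CO2 kinetic factor `CO2_pal^0.5`, uplift
(0.9), land area and the pre-vascular biotic factor 0.25 - with the land
temperature supplied by the same synthetic climate that drives the
vegetation, so biotic and abiotic curves share their forcing. The abiotic
curve has no high-CO2 saturation (the exponential temperature term
compensates the logarithmic temperature-CO2 relation), whereas the biotic
curve saturates through the Michaelis-Menten form of the Farquhar scheme
and the supply limits.

## Numerical choices and degenerate inputs

* All stochastic stages draw from per-(module, cell) sub-streams of one
  master seed (`derive_seed()`), so results are independent of evaluation
  order and bit-reproducible.
* Bisection everywhere monotone roots are needed (internal CO2, carbonate
  proton activity): robust, derivative-free, tolerance documented at the
  call site.
* Ties in the limit minimum are labelled npp before erosion before runoff.
* Degenerate inputs: zero demand leaves `ci = ca`; a barren cell (no
  survivors, or glaciated) carries zero NPP, cover and weathering and is
  excluded from the vegetated area; `composition_factor = 0` gives zero
  dissolved calcium; polar-night months distribute any residual shortwave
  uniformly.
* A zero-amplitude diurnal cycle reproduces the monthly means exactly -
  the identity case used in tests.

## Scales used by the shipped analyses

The numbered scripts under `analysis/` run the experiments at the
package's desk scales: the baseline world at 48 x 24 with 30 species and
50 bookkeeping years (~4 min on one CPU), the sweeps at 24 x 12 with 16
species (about a minute per pipeline run; the disturbance scenarios use
500 bookkeeping years so several disturbance cycles are averaged - the
annual loop is cheap). Unit and acceptance tests use 8 x 8 worlds with
6-20 species and a single hourly year after spin-up. The full
paper-protocol scale (96 x 48, 300 species, 600 years) is reachable
through the same configuration arguments.

## What passing tests do and do not show

The synthetic world emulates gradients, intermittency and limit structure,
not the actual Ordovician circulation: no ocean dynamics, no orography-
aware storm tracks, no proxy assimilation, and rainfall statistics that
are stationary within each month. Passing tests demonstrate that the
mechanisms are implemented faithfully (conservation, monotonicities,
equilibrium chemistry, printed-arithmetic closures) and that the
qualitative findings (CO2 sensitivity with saturation, abiotic-biotic
separation, limit composition, diversity and disturbance effects) are
robust on such a world - they do not certify the study's absolute global
fluxes, which depend on the unavailable GCM forcing. One sensitivity runs
against the published direction and is reported as such: with the
package's electron-cost parameterisation, a stronger CCM (`eta_ccm` 45
versus 8) *lowers* global NPP at 8 PAL - at 2240 ppm ambient CO2 most
active hours are light-limited, so the CCM's electron levy outweighs its
concentration benefit (at modern CO2 the two roughly cancel); the
original model reported a modest positive effect. Known limitations:
the competition scheme is deliberately winner-biased; nutrient recycling
is a single global scalar; the snow scheme is a coarse degree-day model;
and lithology is globally uniform.
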