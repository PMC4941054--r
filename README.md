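# cryptoweather

Desk-scale simulation of global chemical weathering by early non-vascular
vegetation (lichens and bryophytes) under Late Ordovician boundary
conditions, for biogeochemists and paleoclimate modellers who want a
testable, self-contained implementation of the NPP-based weathering
argument.

## The model in brief

Lichens and bryophytes dissolve surface rock to acquire phosphorus. Their
net primary productivity therefore implies a weathering flux:

* **Productivity.** Hundreds of artificial species are Monte-Carlo sampled
  from lichen/bryophyte trait ranges and run hour-by-hour in every land
  grid cell: Farquhar photosynthesis `A = min(Wc, Wj)` at the chloroplast
  CO2 `Cc = eta_CCM * ci`, with `ci` from the balance of demand against
  diffusive supply `D(saturation) * (ca - ci)` (wet thalli are
  diffusion-limited), Q10 respiration tied to capacity through the
  universal ratio `Phi_RR`, and a poikilohydric water reservoir filled by
  rain, dew and snowmelt and emptied by equilibrium-limited evaporation
  and overflow runoff. Species that cannot maintain their biomass die
  out; surviving species are aggregated by competitive area shares.
* **Weathering.** `W_NPP = (NPP / cp) * f_net / r / P_rock` converts NPP
  to dissolved rock volume via the biomass C:P ratio, the net
  resorption-leaching factor (1), the recycling ratio `r` (5:1 for
  pre-vascular ecosystems) and the rock phosphorus concentration
  (1432 g m-3). The realized flux is the cell-wise minimum of `W_NPP`, an
  erosion limit proportional to elevation, and a runoff limit
  `runoff * [Ca]_eq / Ca_rock` with `[Ca]_eq` from the calcite equilibrium
  at the soil CO2 pressure. Where the limits bind, NPP is reduced in
  proportion (phosphorus limitation).
* **References.** Budyko runoff, the GEM-CO2 runoff-lithology model and
  GEOCARB-III-style scaling of abiotic weathering provide present-day and
  abiotic baselines on the same synthetic world.

Because the original gridded GCM forcing is not publicly deposited, the
package generates a synthetic paleogeography and monthly climate with the
right statistical structure (zonal gradients, arid subtropical belts, a
log2 CO2-temperature coupling) and disaggregates it with a stochastic,
exactly conserving weather generator. See `vignettes/methods.Rmd` for the
full account.

## Worked example

```r
library(cryptoweather)

res <- run_experiment(experiment_config(
  "baseline", seed = 1,
  overrides = list(n_lon = 48, n_lat = 24, n_species = 30, n_years = 50)))
res$summary
#>   scenario   npp_gt   gpp_gt     cover biomass_gt weathering_km3
#> 1 baseline 5.430487 7.142491 0.4588335   130.0264       2.166994
#>   potential_npp_gt potential_weathering_km3
#> 1         15.81427                 6.310562
```

About four minutes on one CPU. Reading the row: on this synthetic
Ordovician world the vegetation fixes 15.8 Gt C/yr of potential NPP,
covering 46% of the ice-free land with 130 Gt C of biomass; converting
NPP to phosphorus demand implies 6.3 km3 of rock per year, but erosion
and runoff can only supply enough fresh rock for 2.2 km3/yr, and the
phosphorus shortfall feeds back to a realized NPP of 5.4 Gt C/yr. Over
the vegetated cells, 42% are erosion-limited, 41% NPP-limited and 17%
runoff-limited. The same feedback arithmetic applied to the published
global fluxes (3.6 -> 2.8 km3/yr and 18.7 -> 14.4 Gt C/yr) gives the
22%/23% reductions checked in the test suite.

The numbered scripts under `analysis/` run the remaining study designs:
forcing diagnostics (`01`), the baseline (`02`), the CO2 sweep with the
abiotic GEOCARB curve (`03`), the Hirnantian ice-sheet scenario (`04`),
the species-diversity sweep (`05`), the trait-parameter sensitivity
battery (`06`), present-day reference fluxes (`07`) and single-species
CO2/light/O2 response curves (`08`). Each writes its tables under
`results/` and prints a short narrative, e.g.

```
$ Rscript analysis/08_response_curves.R
Fixture I  at 400 ppm: 5.00 umol m-2 s-1 (anchor ~5)
Fixture II at 400 ppm: 1.99 umol m-2 s-1 (anchor ~2)
```

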