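test_that("Budyko runoff respects its limiting cases and bounds", {
  expect_equal(budyko_runoff(0, 100, 15), 0)
  # zero net radiation: energy-starved limit, runoff = precipitation
  expect_equal(budyko_runoff(800, 0, 15), 800)
  # bounds max(0, P - PET) <= runoff <= P over a parameter grid
  grid <- expand.grid(p = c(10, 100, 500, 1500, 3000),
                      rn = c(0, 20, 80, 150),
                      t = c(-5, 5, 15, 30))
  for (k in seq_len(nrow(grid))) {
    p <- grid$p[k]; rn <- grid$rn[k]; t <- grid$t[k]
    r <- budyko_runoff(p, rn, t)
    s <- cryptoweather:::svp_slope(t)
    pet <- max(0, s / (s + 65) * rn) / 2.45e6 * 8640 * 3600
    expect_gte(r, max(0, p - pet) - 1e-9)
    expect_lte(r, p + 1e-9)
  }
})

test_that("GEM-CO2 fluxes are linear, additive and calibrated", {
  g <- make_grid(8, 8)
  land <- matrix(FALSE, 8, 8); land[3:6, 3:6] <- TRUE
  withr::with_seed(2, {
    runoff <- matrix(runif(64, 0, 600), 8, 8)
  })
  slopes <- calibrate_gem_slopes(runoff, g, land)
  flux <- gem_co2_flux(runoff, g, land, slopes)
  expect_equal(flux$silicate, 3.4e12, tolerance = 1e-9)
  expect_equal(flux$carbonate, 2.1e12, tolerance = 1e-9)
  expect_equal(flux$total, flux$silicate + flux$carbonate)
  # zero runoff, zero flux; doubling runoff doubles the flux
  expect_equal(gem_co2_flux(runoff * 0, g, land, slopes)$total, 0)
  expect_equal(gem_co2_flux(runoff * 2, g, land, slopes)$total,
               2 * flux$total)
})

test_that("GEOCARB scaling is anchored at the reference state", {
  cfg <- geocarb_config(f_uplift = 1, f_land_area = 1)
  ref <- geocarb_abiotic(cfg$t0, 1, cfg)
  present_volume <- ca_flux_to_rock_volume(3.4e12 + 2.1e12)
  expect_equal(ref, 0.25 * present_volume, tolerance = 1e-12)
})

test_that("abiotic weathering increases with temperature and CO2 without
           saturating", {
  temps <- seq(5, 25, by = 1)
  w <- vapply(temps, function(t) geocarb_abiotic(t, 8), numeric(1))
  expect_true(all(diff(w) > 0))
  # CO2 sweep at the coupled land temperature: first differences bounded
  # away from zero (no high-CO2 saturation)
  pal <- c(3, 4, 6, 8, 10, 12, 16, 24)
  land_t <- 4 + 3 * log2(pal / 8)
  wa <- mapply(geocarb_abiotic, land_t, pal)
  slopes <- diff(wa) / diff(pal)
  expect_gt(min(slopes), 0.25 * max(slopes))
})
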