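test_that("NPP = GPP - respiration per species and in aggregate", {
  res <- tiny_cell()
  sp <- res$species
  expect_true(all(abs(sp$npp - (sp$gpp - sp$resp)) <=
                    1e-9 * pmax(abs(sp$gpp), 1)))
  w <- res$species_weights
  expect_equal(res$potential_npp, sum(w * sp$npp), tolerance = 1e-12)
  expect_equal(res$gpp, sum(w * sp$gpp), tolerance = 1e-12)
  expect_gte(res$gpp, res$potential_npp)
})

test_that("surviving species weights sum to one and cover is bounded", {
  res <- tiny_cell()
  expect_gt(res$n_survivors, 0)
  expect_equal(sum(res$species_weights), 1, tolerance = 1e-12)
  expect_true(res$cover >= 0 && res$cover <= 1)
  expect_true(all(res$species_weights >= 0))
})

test_that("a species that cannot cover its respiration dies out", {
  doomed <- fixture_species()[1, , drop = FALSE]
  doomed$resp_ref <- 50  # far above any achievable assimilation
  sp <- rbind(fixture_species(), doomed)
  res <- run_cell(sp, tiny_forcing(), quick_cfg())
  expect_false(res$species$alive[3])
  expect_equal(res$species_weights[3], 0)
  expect_true(any(res$species$alive[1:2]))
})

test_that("frequent disturbance depresses cover and biomass, not NPP", {
  sp <- tiny_species(12, 3)
  r10 <- run_cell(sp, tiny_forcing(),
                  veg_config(tau_d_years = 10, n_hourly_years = 1,
                             n_years = 500))
  r250 <- run_cell(sp, tiny_forcing(),
                   veg_config(tau_d_years = 250, n_hourly_years = 1,
                              n_years = 500))
  expect_lt(r10$cover, 0.7 * r250$cover)
  expect_lt(r10$biomass, 0.7 * r250$biomass)
  expect_equal(r10$potential_npp, r250$potential_npp, tolerance = 0.05)
})

test_that("cell results are deterministic and reject bad forcing", {
  a <- run_cell(tiny_species(5), tiny_forcing(), quick_cfg())
  b <- run_cell(tiny_species(5), tiny_forcing(), quick_cfg())
  expect_identical(a, b)
  bad <- tiny_forcing()
  bad$sw <- bad$sw[1:100]
  expect_error(run_cell(tiny_species(5), bad, quick_cfg()), "8640")
})

test_that("the dominant species under high CO2 has at least the
           photosynthetic capacity of the low-CO2 dominant", {
  f <- tiny_forcing()
  wins <- 0; n_rep <- 8
  for (s in seq_len(n_rep)) {
    sp <- sample_species(20, s)
    hi <- run_cell(sp, f, quick_cfg(co2_pal = 24))
    lo <- run_cell(sp, f, quick_cfg(co2_pal = 360 / 280, o2 = 0.21))
    if (hi$barren || lo$barren) { n_rep <- n_rep - 1; next }
    v_hi <- sp$vcmax_ref[which.max(hi$species_weights)]
    v_lo <- sp$vcmax_ref[which.max(lo$species_weights)]
    wins <- wins + (v_hi >= v_lo)
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("species NPP is non-decreasing and saturating in ambient CO2", {
  sp <- tiny_species(6, 5)
  pal <- c(1, 2, 4, 8, 16, 32, 64)
  for (s in seq_len(nrow(sp))) {
    npp <- vapply(pal * 280, function(ca)
      photosynthesis_rate(sp[s, , drop = FALSE], 250, 20, 1, ca,
                          o2 = 0.14)$npp, numeric(1))
    expect_true(all(diff(npp) >= -1e-10))
    # saturation: the response flattens at high CO2
    slopes <- diff(npp) / diff(pal * 280)
    expect_lt(slopes[length(slopes)], 0.5 * max(slopes))
  }
})
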