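test_that("an all-glaciated domain carries no vegetation", {
  g <- make_grid(8, 8)
  p <- generate_paleogeography(g, 2)
  p$glacier_mask <- p$land_mask  # prescribe ice over every land cell
  cl <- generate_monthly_climate(p, 8, 2)
  veg <- run_grid(p, cl, tiny_species(3), 2, quick_cfg())
  expect_true(all(veg$potential_npp == 0))
  expect_equal(sum(veg$vegetated), 0)
  expect_equal(sum(veg$available), 0)
})

test_that("zonal NPP peaks at the warm wet equator rather than the poles", {
  run <- tiny_pipeline()
  veg <- run$veg
  g <- run$paleo$grid
  lat <- matrix(rep(g$lat_centers, each = g$n_lon), g$n_lon, g$n_lat)
  tropics <- veg$vegetated & abs(lat) < 40
  polar <- veg$vegetated & abs(lat) > 55
  expect_gt(area_mean(veg$potential_npp, g, tropics),
            area_mean(veg$potential_npp, g, polar))
})

test_that("grid runs are reproducible and reject mismatched grids", {
  run <- tiny_pipeline()
  veg2 <- run_grid(run$paleo, run$climate, run$species, 11, quick_cfg())
  expect_equal(veg2$potential_npp, run$veg$potential_npp)
  other <- generate_monthly_climate(generate_paleogeography(
    make_grid(4, 4), 1), 8, 1)
  expect_error(run_grid(run$paleo, other, run$species, 1, quick_cfg()),
               "do not match")
})

test_that("dominant-species extraction returns a valid parameter row", {
  run <- tiny_pipeline()
  dom <- dominant_species(run$veg)
  expect_s3_class(dom, "species_params")
  expect_equal(nrow(dom), 1)
  barren <- run$veg
  barren$vegetated[] <- FALSE
  expect_null(dominant_species(barren))
})
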