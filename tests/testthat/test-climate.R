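test_that("CO2 doubling shifts land temperature by the configured sensitivity", {
  p <- tiny_paleo()
  g <- tiny_grid()
  c8 <- generate_monthly_climate(p, 8, 42)
  c16 <- generate_monthly_climate(p, 16, 42)
  t8 <- area_mean(apply(c8$temp, c(1, 2), mean), g, p$land_mask)
  t16 <- area_mean(apply(c16$temp, c(1, 2), mean), g, p$land_mask)
  expect_equal(t16 - t8, 3, tolerance = 1e-10)

  # below the reference level an extra cooling term steepens the response
  c4 <- generate_monthly_climate(p, 4, 42)
  c2 <- generate_monthly_climate(p, 2, 42)
  t4 <- area_mean(apply(c4$temp, c(1, 2), mean), g, p$land_mask)
  t2 <- area_mean(apply(c2$temp, c(1, 2), mean), g, p$land_mask)
  expect_gt(t4 - t2, 3)  # more than the log2 law alone
})

test_that("zonal structure: poleward cooling and subtropical arid belts", {
  g <- make_grid(24, 16)
  p <- generate_paleogeography(g, 3)
  cl <- generate_monthly_climate(p, 8, 3)
  zt <- zonal_mean <- colSums(apply(cl$temp, c(1, 2), mean) * g$cell_area) /
    colSums(g$cell_area)
  lats <- g$lat_centers
  nh <- zt[lats > 0][order(lats[lats > 0])]
  sh <- zt[lats < 0][order(-lats[lats < 0])]
  expect_true(all(diff(nh) <= 1))  # non-increasing poleward, 1 degC noise
  expect_true(all(diff(sh) <= 1))
  # annual rainfall minimum within +/-10 deg of the 30 deg belts
  pr <- colSums(apply(cl$rain + cl$snow, c(1, 2), sum) * g$cell_area) /
    colSums(g$cell_area)
  for (hemi in list(lats > 5 & lats < 60, lats < -5 & lats > -60)) {
    expect_lt(abs(abs(lats[hemi][which.min(pr[hemi])]) - 30), 10)
  }
})

test_that("climate fields satisfy physical bounds and determinism", {
  cl <- tiny_climate()
  expect_true(all(cl$rh >= 0 & cl$rh <= 1))
  expect_true(all(cl$rain >= 0))
  expect_true(all(cl$snow >= 0))
  expect_true(all(cl$sw >= 0))
  expect_identical(cl, generate_monthly_climate(tiny_paleo(), 8, 42))
  expect_error(generate_monthly_climate(tiny_paleo(), -1, 1), "positive")
})
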