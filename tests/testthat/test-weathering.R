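test_that("phosphorus demand follows the stoichiometric bookkeeping", {
  st <- stoichiometry()
  expect_equal(phosphorus_demand(0, st), 0)
  # npp 5, C:P 350, net factor 1, recycling 5 -> ~2.86e-3 g P m-2 yr-1
  expect_equal(phosphorus_demand(5, st), 5 / 350 / 5, tolerance = 1e-12)
  expect_equal(phosphorus_demand(5, st), 2.857e-3, tolerance = 1e-3)
  # recycling 50 vs 5: demand 10x smaller
  st50 <- stoichiometry(recycling_ratio = 50)
  expect_equal(phosphorus_demand(7, st), 10 * phosphorus_demand(7, st50))
  expect_error(stoichiometry(recycling_ratio = 0.5), ">= 1")
  expect_error(phosphorus_demand(-1, st), ">= 0")
})

test_that("NPP-based weathering reproduces the desert reference value", {
  rock <- rock_geochem()
  w <- npp_weathering(phosphorus_demand(5, stoichiometry()), rock)
  expect_equal(w * 1000, 0.002, tolerance = 0.005)  # mm/yr
  expect_equal(npp_weathering(0, rock), 0)
  half <- rock_geochem(p_conc = rock$p_conc / 2)
  expect_equal(npp_weathering(1, half), 2 * npp_weathering(1, rock))
})

test_that("the erosion limit is linear in elevation", {
  expect_equal(erosion_limit(0), 0)
  expect_equal(erosion_limit(2000), 2 * erosion_limit(1000))
  expect_equal(erosion_limit(1000) * 1000, 0.06, tolerance = 1e-12)  # mm/yr
  expect_error(erosion_limit(-5), ">= 0")
})

test_that("the runoff limit is linear in runoff and zero when arid", {
  rock <- rock_geochem()
  ca <- calcite_equilibrium_ca(soil_chemistry())
  expect_equal(runoff_limit(0, ca, rock), 0)
  expect_equal(runoff_limit(600, ca, rock), 2 * runoff_limit(300, ca, rock))
})

test_that("the minimum of the limits is taken with the tie priority", {
  res <- apply_limits(3.6, 2.0, 5.0)
  expect_equal(res$w_realized, 2.0)
  expect_equal(res$limiting_factor, "erosion")
  res <- apply_limits(1, 1, 1)
  expect_equal(res$limiting_factor, "npp")
  # random fields: min contract and label consistency
  withr::with_seed(4, {
    a <- matrix(runif(60), 6); b <- matrix(runif(60), 6)
    c <- matrix(runif(60), 6)
    res <- apply_limits(a, b, c)
    expect_true(all(res$w_realized <= a & res$w_realized <= b &
                      res$w_realized <= c))
    expect_true(all((res$limiting_factor == "npp") == (a <= pmin(b, c))))
  })
  expect_error(apply_limits(matrix(1, 2, 2), matrix(1, 3, 3), 1), "shape")
})

test_that("phosphorus limitation scales NPP with the weathering ratio", {
  expect_equal(phosphorus_limited_npp(100, 2, 2), 100)
  expect_equal(phosphorus_limited_npp(100, 2, 1), 50)
  expect_equal(phosphorus_limited_npp(100, 0, 0), 100)  # no demand
  expect_error(phosphorus_limited_npp(100, 1, 2), "exceed")
})

test_that("calcium fluxes convert to rock volumes via the calibrated rock", {
  expect_equal(ca_flux_to_rock_volume(7.7e12), 1.8, tolerance = 1e-6)
  expect_equal(ca_flux_to_rock_volume(5.5e12), 1.3, tolerance = 0.04)
  expect_equal(ca_flux_to_rock_volume(0), 0)
})

test_that("global totals integrate uniform fields exactly", {
  g <- make_grid(8, 8)
  land <- matrix(TRUE, 8, 8)
  f <- matrix(3e-5, 8, 8)
  expect_equal(area_sum(f, g, land), 3e-5 * sum(g$cell_area))
  half <- land; half[, 1:4] <- FALSE
  expect_equal(area_sum(f, g, half), 3e-5 * sum(g$cell_area[, 5:8]))
  # grid refinement leaves totals of a smooth field nearly unchanged
  tot <- sapply(c(24, 96), function(n) {
    gg <- make_grid(n, n / 2)
    lat <- matrix(rep(gg$lat_centers, each = n), n, n / 2)
    area_sum(1 + cos(lat * pi / 180), gg)
  })
  expect_equal(tot[1], tot[2], tolerance = 0.01)
})

test_that("the pipeline weathering result keeps its internal consistency", {
  run <- tiny_pipeline()
  w <- run$weathering
  m <- run$veg$vegetated
  expect_true(all(w$w_realized[m] <= w$w_npp[m] + 1e-15))
  expect_true(all(w$w_realized[m] <= w$w_erosion[m] + 1e-15))
  expect_true(all(w$w_realized[m] <= w$w_runoff[m] + 1e-15))
  expect_true(all(w$realized_npp[m] <= run$veg$potential_npp[m] + 1e-12))
})

test_that("directional responses: recycling ratio and soil CO2", {
  run <- tiny_pipeline()
  g <- run$paleo$grid
  tot_w <- function(stoich = stoichiometry(), soil = soil_chemistry()) {
    w <- weathering_from_veg(run$veg, run$paleo, stoich = stoich,
                             soil = soil)
    t <- global_totals(w, run$veg, g)
    c(w = t$weathering_km3, npp = t$npp_gt)
  }
  r1 <- tot_w(stoichiometry(recycling_ratio = 1))
  r5 <- tot_w(stoichiometry(recycling_ratio = 5))
  r50 <- tot_w(stoichiometry(recycling_ratio = 50))
  expect_true(r1["w"] >= r5["w"] && r5["w"] >= r50["w"])
  expect_true(r1["npp"] <= r5["npp"] && r5["npp"] <= r50["npp"])
  expect_gt(r1["w"], r50["w"])

  lo <- tot_w(soil = soil_chemistry(3000))
  hi <- tot_w(soil = soil_chemistry(30000))
  expect_gte(hi["w"], lo["w"])
  expect_gt(hi["w"], lo["w"] * 1.0001)  # runoff limit binds somewhere
})

test_that("halving potential NPP reduces weathering by less than half", {
  run <- tiny_pipeline()
  g <- run$paleo$grid
  veg_half <- run$veg
  veg_half$potential_npp <- run$veg$potential_npp * 0.5
  veg_half$gpp <- run$veg$gpp * 0.5
  w_full <- global_totals(weathering_from_veg(run$veg, run$paleo),
                          run$veg, g)$weathering_km3
  w_half <- global_totals(weathering_from_veg(veg_half, run$paleo),
                          veg_half, g)$weathering_km3
  expect_gt(w_half, 0.5 * w_full)
  expect_lt(w_half, w_full)
})
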