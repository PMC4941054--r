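one_species <- function(...) {
  p <- fixture_species()[1, , drop = FALSE]
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

test_that("assimilation vanishes without light and at the compensation point", {
  p <- one_species()
  expect_equal(farquhar_gpp(p, par = 0, temp = 20, ci = 400), 0)
  # Cc = gamma* => Wc = Wj = 0
  gs <- cryptoweather:::farquhar_kinetics(20, 0.21)$gamma_star
  expect_equal(farquhar_gpp(p, 500, 20, ci = gs / p$eta_ccm), 0,
               tolerance = 1e-12)
  expect_gt(farquhar_gpp(p, 500, 20, ci = 2 * gs / p$eta_ccm), 0)
})

test_that("assimilation is non-decreasing and saturating in internal CO2", {
  p <- one_species()
  ci <- seq(5, 3000, by = 5)
  a <- farquhar_gpp(p, 250, 20, ci)
  expect_true(all(diff(a) >= -1e-12))
  # concave (second differences <= 0) once past the compensation point
  high <- ci > 100
  expect_true(all(diff(diff(a[high])) <= 1e-10))
  expect_true(is.finite(a[ci == 2240] / a[ci == 400]))
})

test_that("lowering O2 from 21% to 14% increases assimilation at fixed ci", {
  p <- one_species()
  for (ci in c(100, 200, 400)) {
    expect_gt(farquhar_gpp(p, 250, 20, ci, o2 = 0.14),
              farquhar_gpp(p, 250, 20, ci, o2 = 0.21))
  }
  expect_error(farquhar_gpp(p, -1, 20, 400), "non-negative")
})

test_that("respiration follows the Q10 law anchored at 20 degC", {
  p <- one_species(q10 = 2.3)
  expect_equal(respiration(p, 20), p$resp_ref)
  expect_equal(respiration(p, 30), 2.3 * p$resp_ref)
  # doubling phi_rr at fixed capacity halves respiration
  sp1 <- sample_species(5, 1, phi_rr = 15)
  sp2 <- sample_species(5, 1, phi_rr = 30)
  expect_equal(sp1$vcmax_ref, sp2$vcmax_ref)
  expect_equal(respiration(sp2, 25), respiration(sp1, 25) / 2)
})

test_that("diffusivity decreases with water content, anchored at saturation", {
  p <- one_species()
  s <- seq(0, 1, by = 0.1)
  d <- co2_diffusivity(p, s)
  expect_true(all(diff(d) < 0))
  expect_equal(d[11], p$d_co2_sat)
  expect_error(co2_diffusivity(p, 1.2), "saturation")
})

test_that("internal CO2 balances supply against demand", {
  p <- one_species()
  # no demand, no gradient
  expect_equal(internal_co2(p, 0.5, 400, 0)$ci, 400)
  # wetter thallus: lower diffusivity, lower ci at equal demand
  ci_wet <- internal_co2(p, 1, 400, 2)$ci
  ci_dry <- internal_co2(p, 0.5, 400, 2)$ci
  expect_lt(ci_wet, ci_dry)
  # doubling the ambient raises ci at fixed demand
  expect_gt(internal_co2(p, 1, 800, 2)$ci, ci_wet)
})

test_that("the coupled (ci, A) solution matches a brute-force search", {
  p <- one_species()
  demand <- function(ci) farquhar_gpp(p, 250, 20, ci)
  sol <- internal_co2(p, 1, 400, demand)
  g <- co2_diffusivity(p, 1) * 41.6
  # brute force on a fine grid
  grid <- seq(0, 400, length.out = 200001)
  resid <- abs(g * (400 - grid) - demand(grid))
  expect_equal(sol$ci, grid[which.min(resid)], tolerance = 1e-4)
  expect_equal(g * (400 - sol$ci), sol$A, tolerance = 1e-6)
  # photosynthesis_rate agrees with the generic solver
  pr <- photosynthesis_rate(p, 250, 20, 1, 400)
  expect_equal(pr$ci, sol$ci, tolerance = 1e-6)
  expect_equal(pr$A, sol$A, tolerance = 1e-6)
})
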