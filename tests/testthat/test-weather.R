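test_that("hourly series conserve monthly means and totals", {
  cl <- tiny_climate()
  for (cell in list(c(3, 4), c(1, 2), c(8, 1))) {
    f <- downscale_to_hourly(cl, 9, i = cell[1], j = cell[2])
    for (m in 1:12) {
      sel <- f$month == m
      mon <- cell_idx <- list(
        temp = cl$temp[cell[1], cell[2], m],
        sw = cl$sw[cell[1], cell[2], m],
        lw = cl$lw[cell[1], cell[2], m],
        rh = cl$rh[cell[1], cell[2], m],
        wind = cl$wind[cell[1], cell[2], m])
      # states: monthly mean
      for (v in names(mon)) {
        ref <- mon[[v]]
        expect_lt(abs(mean(f[[v]][sel]) - ref), 1e-6 * max(abs(ref), 1))
      }
      # fluxes: monthly totals
      expect_lt(abs(sum(f$rain[sel]) - cl$rain[cell[1], cell[2], m]),
                1e-6 * max(cl$rain[cell[1], cell[2], m], 1))
      expect_lt(abs(sum(f$snow[sel]) - cl$snow[cell[1], cell[2], m]),
                1e-6 * max(cl$snow[cell[1], cell[2], m], 1))
    }
  }
})

test_that("generated hourly drivers respect physical bounds", {
  f <- tiny_forcing()
  expect_true(all(f$rh >= 0 & f$rh <= 1))
  expect_true(all(f$sw >= 0))
  expect_true(all(f$rain >= 0 & f$snow >= 0))
  expect_length(f$sw, 8640)
})

test_that("the generator is deterministic and seed-sensitive", {
  a <- downscale_to_hourly(tiny_climate(), 5, i = 3, j = 4)
  b <- downscale_to_hourly(tiny_climate(), 5, i = 3, j = 4)
  expect_identical(a, b)
  c <- downscale_to_hourly(tiny_climate(), 6, i = 3, j = 4)
  expect_false(identical(a$rain, c$rain))
})

test_that("zero diurnal amplitude gives constant within-month temperature", {
  f <- downscale_to_hourly(tiny_climate(), 5, i = 3, j = 4,
                           diurnal_temp_amplitude = 0)
  cl <- tiny_climate()
  for (m in c(1, 7)) {
    expect_true(all(f$temp[f$month == m] == cl$temp[3, 4, m]))
    expect_true(all(f$rh[f$month == m] == cl$rh[3, 4, m]))
  }
})

test_that("a 90 mm month rains exactly 90 mm, intermittently", {
  mon <- list(sw = rep(200, 12), lw = rep(350, 12), rain = rep(90, 12),
              snow = rep(0, 12), temp = rep(15, 12), wind = rep(3, 12),
              rh = rep(0.7, 12), lat = 10)
  f <- downscale_to_hourly(mon, 2)
  expect_equal(sum(f$rain[f$month == 1]), 90, tolerance = 1e-12)
  # wet events are episodic, not uniform drizzle
  expect_gt(mean(f$rain[f$month == 1] == 0), 0.5)
})

test_that("negative monthly precipitation is rejected", {
  mon <- list(sw = rep(200, 12), lw = rep(350, 12), rain = rep(-1, 12),
              snow = rep(0, 12), temp = rep(15, 12), wind = rep(3, 12),
              rh = rep(0.7, 12), lat = 10)
  expect_error(downscale_to_hourly(mon, 2), "non-negative")
})
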