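hour_of <- function(sw = 0, lw = NULL, rain = 0, temp = 15, rh = 0.5,
                    snow = 0) {
  if (is.null(lw)) lw <- 5.670374e-8 * (temp + 273.15)^4  # zero net radiation
  list(sw = sw, lw = lw, rain = rain, temp = temp, rh = rh, snow = snow)
}

test_that("overflow above storage capacity leaves as runoff", {
  p <- fixture_species()[1, , drop = FALSE]  # theta_max = 4
  st <- list(water_content = 3.5)
  res <- step_water(st, hour_of(rain = 2), p)
  # zero net radiation => no evaporation; runoff is the overflow
  expect_equal(res$evap, 0)
  expect_equal(res$runoff, 2 - (4 - 3.5))
  expect_equal(res$state$water_content, 4)
})

test_that("no input and no net radiation leaves storage unchanged", {
  p <- fixture_species()[1, , drop = FALSE]
  st <- list(water_content = 1.7)
  res <- step_water(st, hour_of(), p)
  expect_equal(res$state$water_content, 1.7)
  expect_equal(res$runoff + res$evap + res$dew, 0)
})

test_that("dew forms only on humid, mild nights", {
  p <- fixture_species()[1, , drop = FALSE]
  expect_gt(step_water(list(water_content = 0),
                       hour_of(rh = 0.97, temp = 10), p)$dew, 0)
  expect_equal(step_water(list(water_content = 0),
                          hour_of(rh = 0.97, temp = 10, sw = 300), p)$dew, 0)
  expect_equal(step_water(list(water_content = 0),
                          hour_of(rh = 0.5, temp = 10), p)$dew, 0)
})

test_that("the water budget closes exactly over a random month", {
  withr::with_seed(99, {
    p <- fixture_species()[1, , drop = FALSE]
    st <- list(water_content = 2)
    total_in <- total_out <- 0
    for (t in 1:720) {
      h <- hour_of(sw = runif(1, 0, 600), rain = rexp(1, 2) * (runif(1) < 0.1),
                   temp = runif(1, 5, 25), rh = runif(1, 0.3, 1))
      res <- step_water(st, h, p)
      total_in <- total_in + h$rain + res$dew
      total_out <- total_out + res$evap + res$runoff
      st <- res$state
    }
    expect_lt(abs(total_in - total_out - (st$water_content - 2)), 1e-9)
  })
})

test_that("snowpack melts when warm and glaciates under persistent accumulation", {
  cfg <- snow_config()
  # warm, no snowfall: non-increasing
  sn <- list(swe = 50, glaciated = FALSE)
  for (t in 1:48) {
    res <- step_snow(sn, list(snow = 0, temp = 5), cfg)
    expect_lte(res$snow$swe, sn$swe)
    sn <- res$snow
  }
  # perpetual -20 degC with steady snowfall exceeding lateral loss:
  # 50-year column integration glaciates the cell
  sn <- list(swe = 0, glaciated = FALSE)
  snowfall_h <- 500 / 8640  # 500 mm/yr
  for (y in 1:50) {
    for (t in 1:96) {  # representative sample of hours, scaled
      res <- step_snow(sn, list(snow = snowfall_h * 90, temp = -20), cfg)
      sn <- res$snow
    }
  }
  expect_true(sn$glaciated)
})

test_that("water closure holds inside the hourly cell integration", {
  res <- tiny_cell()
  sp <- res$species
  resid <- abs(sp$water_in - sp$water_evap - sp$water_runoff - sp$d_storage)
  expect_true(all(resid < 1e-9))
})
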