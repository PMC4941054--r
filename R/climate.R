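# Synthetic monthly climate generator. Emulates the statistical structure of
# a paleo-GCM monthly climatology: poleward-cooling zonal temperature,
# equatorial rain belt with arid subtropics and mid-latitude storm tracks,
# hemispherically opposed seasonal cycles, and an imposed log2 CO2-temperature
# coupling with an optional extra cooling term at low CO2.

# Month centres of a 360-day year as fractions of the year.
month_centers <- function() ((1:12) - 0.5) / 12

# Solar declination (deg) at month m of a 12-month year (January = 1).
month_declination <- function(m) {
  -23.44 * cos(2 * pi * (m - 0.5) / 12)
}

# Daily-mean top-of-atmosphere insolation (W m-2) for latitude phi (deg)
# and month m; s0 is the solar constant.
toa_insolation <- function(lat_deg, m, s0) {
  phi <- lat_deg * pi / 180
  dec <- month_declination(m) * pi / 180
  x <- -tan(phi) * tan(dec)
  h0 <- acos(pmin(1, pmax(-1, x)))  # half day length (radians)
  q <- (s0 / pi) * (h0 * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(h0))
  pmax(0, q)
}

#' Generate synthetic monthly climate fields
#'
#' Produces the seven monthly drivers used by the vegetation model
#' (downwelling shortwave and longwave radiation, rainfall, snowfall, air
#' temperature, wind speed and relative humidity) on the paleogeography's
#' grid, with:
#' \itemize{
#'   \item zonal-mean temperature decreasing from equator to pole, a lapse
#'     correction over elevated land, and a seasonal cycle in hemispheric
#'     phase opposition;
#'   \item an imposed CO2-temperature coupling
#'     `dT = sensitivity * log2(co2_pal / co2_ref_pal)` plus an extra
#'     quadratic cooling term below the reference CO2 (the land response to
#'     CO2 steepens at low CO2);
#'   \item annual rainfall maximal near the (seasonally migrating) equatorial
#'     rain belt, minimal in the subtropical belts near +/-30 deg, with a
#'     secondary mid-latitude maximum;
#'   \item shortwave radiation from daily-mean top-of-atmosphere insolation
#'     under a rainfall-dependent atmospheric transmission.
#' }
#'
#' @param paleo a `paleogeography`.
#' @param co2_pal atmospheric CO2 in PAL (1 PAL = 280 ppm); must be > 0.
#' @param seed integer seed for the multiplicative weather-pattern noise.
#' @param sensitivity land temperature change per CO2 doubling (deg C,
#'   default 3).
#' @param co2_ref_pal reference CO2 level at which the base climatology is
#'   defined (default 8 PAL, the Ordovician baseline).
#' @param low_co2_extra coefficient of the extra cooling term
#'   `low_co2_extra * max(0, -log2(co2/co2_ref))^2` (deg C; 0 disables).
#' @param s0 solar constant (W m-2; default 1307, ~96% of the modern value
#'   for the Late Ordovician sun).
#' @param precip_per_degree fractional increase of precipitation per degC
#'   of CO2-driven warming (Clausius-Clapeyron-like scaling, default
#'   0.02).
#' @return object of class `monthly_climate`: list of arrays
#'   `c(n_lon, n_lat, 12)` named `sw`, `lw`, `rain`, `snow`, `temp`,
#'   `wind`, `rh` (units W m-2, W m-2, mm/month, mm/month water equivalent,
#'   deg C, m s-1, fraction), plus `grid` and `co2_pal`.
#' @export
generate_monthly_climate <- function(paleo, co2_pal, seed,
                                     sensitivity = 3,
                                     co2_ref_pal = 8,
                                     low_co2_extra = 0.5,
                                     s0 = 1307,
                                     precip_per_degree = 0.02) {
  if (!inherits(paleo, "paleogeography")) {
    stop("`paleo` must be a paleogeography", call. = FALSE)
  }
  assert_positive(co2_pal)
  grid <- paleo$grid
  n_lon <- grid$n_lon; n_lat <- grid$n_lat
  lat <- grid_lat_matrix(grid)

  lr <- log2(co2_pal / co2_ref_pal)
  dT <- sensitivity * lr - low_co2_extra * max(0, -lr)^2

  withr::with_seed(derive_seed(seed, 202L), {
    t_noise <- smooth_field(matrix(stats::rnorm(n_lon * n_lat, sd = 1.5),
                                   n_lon, n_lat), passes = 2L)
    wet_noise <- exp(smooth_field(matrix(stats::rnorm(n_lon * n_lat, sd = 0.8),
                                         n_lon, n_lat), passes = 2L))
    rh_noise <- smooth_field(matrix(stats::rnorm(n_lon * n_lat, sd = 0.1),
                                    n_lon, n_lat), passes = 2L)
    wind_noise <- smooth_field(matrix(stats::rnorm(n_lon * n_lat, sd = 1),
                                      n_lon, n_lat), passes = 2L)
  })
  wet_noise <- wet_noise / mean(wet_noise)

  dims <- c(n_lon, n_lat, 12L)
  sw <- lw <- rain <- snow <- temp <- wind <- rh <- array(0, dims)

  t_ann <- 28 - 42 * sin(lat * pi / 180)^2 + dT +
    t_noise - 6.5e-3 * paleo$elevation
  seas_amp <- 2 + 14 * sin(lat * pi / 180)^2
  wind_base <- pmax(0.5, 3 + 5 * abs(sin(2 * lat * pi / 180)) + wind_noise)

  for (m in 1:12) {
    phase <- cos(2 * pi * (m - 1) / 12)       # +1 in Jan (SH summer)
    temp_m <- t_ann - sign(lat) * seas_amp * phase
    itcz <- -8 * phase                         # rain-belt latitude (deg)
    p_m <- (220 * exp(-((lat - itcz) / 12)^2) +
            70 * exp(-((abs(lat) - 55) / 15)^2) + 15) * wet_noise *
      max(0.1, 1 + precip_per_degree * dT)
    f_snow <- 1 / (1 + exp(temp_m / 1.5))
    cloud <- p_m / (p_m + 60)
    sw_m <- toa_insolation(lat, m, s0) * (0.75 - 0.35 * cloud)
    rh_m <- pmin(0.98, pmax(0.05, 0.45 + 0.5 * p_m / (p_m + 60) + rh_noise))
    lw_m <- (0.70 + 0.20 * cloud) * .const$sigma_sb * (temp_m + 273.15)^4

    temp[, , m] <- temp_m
    rain[, , m] <- p_m * (1 - f_snow)
    snow[, , m] <- p_m * f_snow
    sw[, , m] <- sw_m
    lw[, , m] <- lw_m
    rh[, , m] <- rh_m
    wind[, , m] <- wind_base
  }

  structure(
    list(sw = sw, lw = lw, rain = rain, snow = snow, temp = temp,
         wind = wind, rh = rh, grid = grid, co2_pal = co2_pal),
    class = "monthly_climate"
  )
}

#' @export
print.monthly_climate <- function(x, ...) {
  g <- x$grid
  tm <- mean(apply(x$temp, c(1, 2), mean))
  pm <- mean(apply(x$rain + x$snow, c(1, 2), sum))
  cat(sprintf(
    "<monthly_climate> %d x %d x 12, CO2 %.3g PAL, global mean T %.1f degC, mean precip %.0f mm/yr\n",
    g$n_lon, g$n_lat, x$co2_pal, tm, pm))
  invisible(x)
}

# Extract the 12-month series of all variables for one cell (i, j).
cell_monthly <- function(climate, i, j) {
  list(sw = climate$sw[i, j, ], lw = climate$lw[i, j, ],
       rain = climate$rain[i, j, ], snow = climate$snow[i, j, ],
       temp = climate$temp[i, j, ], wind = climate$wind[i, j, ],
       rh = climate$rh[i, j, ],
       lat = climate$grid$lat_centers[j])
}
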