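# Poikilohydric water balance and snow scheme. The thallus is a single
# reservoir per species, filled by rain, dew and snowmelt and emptied by
# evaporation (bounded by an equilibrium-evaporation energy limit) with
# overflow above the storage capacity leaving as runoff. The water budget
# closes exactly: input - evaporation - runoff = change in storage.

# Equilibrium-evaporation potential rate for one hour (kg m-2 h-1).
# Net radiation from shortwave (with species albedo), incoming longwave
# and grey-body emission at air temperature.
equilibrium_evap_hour <- function(sw, lw, temp, albedo) {
  rn <- (1 - albedo) * sw + lw - .const$sigma_sb * (temp + 273.15)^4
  s <- svp_slope(temp)
  pmax(0, s / (s + .const$gamma_psy) * rn) / .const$lambda_vap *
    .const$sec_per_hour
}

# Dew deposition for one hour (kg m-2 h-1): forms at night when the air is
# near saturation and above freezing.
dew_hour <- function(sw, rh, temp, dew_rate = 0.03, rh_threshold = 0.95) {
  ifelse(sw <= 1 & rh >= rh_threshold & temp > 0, dew_rate, 0)
}

# One reservoir update, vectorised over species. Evaporation is bounded by
# the available water; overflow above theta_max becomes runoff.
water_step_vec <- function(storage, input, epot, theta_max) {
  avail <- storage + input
  evap <- pmin(avail, epot)
  after <- avail - evap
  runoff <- pmax(0, after - theta_max)
  list(storage = after - runoff, runoff = runoff, evap = evap)
}

#' Advance the thallus water reservoir by one hour
#'
#' @param state list with `water_content` (kg m-2).
#' @param hour list with scalars `sw`, `lw`, `rain` (mm/h), `temp`, `rh`
#'   (one hour of an `hourly_forcing`).
#' @param params one species (row of a `species_params`).
#' @param melt snowmelt water input this hour (kg m-2, default 0).
#' @param dew_rate,rh_threshold dew parameterisation, see details in the
#'   vignette.
#' @return list with updated `state`, and `runoff`, `dew`, `evap`
#'   (kg m-2 for the hour).
#' @export
step_water <- function(state, hour, params, melt = 0,
                       dew_rate = 0.03, rh_threshold = 0.95) {
  dew <- dew_hour(hour$sw, hour$rh, hour$temp, dew_rate, rh_threshold)
  epot <- equilibrium_evap_hour(hour$sw, hour$lw, hour$temp, params$albedo)
  input <- hour$rain + dew + melt
  upd <- water_step_vec(state$water_content, input, epot, params$theta_max)
  list(state = list(water_content = upd$storage),
       runoff = upd$runoff, dew = dew, evap = upd$evap)
}

#' Default snow-scheme parameters
#'
#' Degree-day melt, a lateral (glacier-flow) loss proportional to the
#' snowpack, and the snow-water equivalent above which a cell counts as
#' glaciated.
#'
#' @param ddf_mm_per_degday degree-day melt factor (mm water per degC day).
#' @param lateral_loss_per_year fractional lateral export of the pack per
#'   year.
#' @param glacier_swe snow-water equivalent threshold for glaciation
#'   (kg m-2).
#' @param cover_swe snow-water equivalent above which vegetation is
#'   considered snow-covered and inactive (kg m-2).
#' @return list of parameters.
#' @export
snow_config <- function(ddf_mm_per_degday = 3,
                        lateral_loss_per_year = 0.1,
                        glacier_swe = 1000,
                        cover_swe = 5) {
  list(ddf_mm_per_degday = ddf_mm_per_degday,
       lateral_loss_per_year = lateral_loss_per_year,
       glacier_swe = glacier_swe,
       cover_swe = cover_swe)
}

#' Advance the snowpack by one hour
#'
#' `SWE` gains snowfall and loses degree-day melt and a lateral export
#' proportional to the pack. The `glaciated` flag is sticky: once the pack
#' exceeds the glacier threshold the cell is considered glaciated (a
#' prescribed glacier mask, where present, overrides the dynamic state at
#' the grid level).
#'
#' @param snow list with `swe` (kg m-2) and `glaciated` (logical).
#' @param hour list with scalars `snow` (mm/h water equivalent) and `temp`.
#' @param melt_cfg parameters from [snow_config()].
#' @return list with updated `snow` and the `melt` released this hour
#'   (kg m-2).
#' @export
step_snow <- function(snow, hour, melt_cfg = snow_config()) {
  swe <- snow$swe + hour$snow
  melt <- min(swe, melt_cfg$ddf_mm_per_degday * max(hour$temp, 0) / 24)
  swe <- swe - melt
  lateral <- swe * melt_cfg$lateral_loss_per_year / .const$hours_per_year
  swe <- swe - lateral
  list(snow = list(swe = swe,
                   glaciated = isTRUE(snow$glaciated) ||
                     swe > melt_cfg$glacier_swe),
       melt = melt)
}
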