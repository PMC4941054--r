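# Reference computations: Budyko runoff from annual climate, the GEM-CO2
# runoff-lithology weathering model, and GEOCARB-III-style scaling of an
# abiotic Ordovician weathering flux from present-day component fluxes.

#' Runoff from the Budyko curve with equilibrium-evaporation PET
#'
#' Potential evaporation is the equilibrium rate
#' `PET = s/(s+gamma) * Rn / lambda`; actual evaporation follows the
#' Budyko curve `E/P = sqrt(phi tanh(1/phi) (1 - exp(-phi)))` with aridity
#' index `phi = PET/P`, and runoff is `P - E`. Satisfies
#' `max(0, P - PET) <= runoff <= P`.
#'
#' @param precip annual precipitation (mm yr-1, >= 0); vectorised.
#' @param net_radiation annual-mean net radiation (W m-2).
#' @param temp annual-mean temperature (degC).
#' @return runoff (mm yr-1).
#' @export
budyko_runoff <- function(precip, net_radiation, temp) {
  if (any(precip < 0, na.rm = TRUE)) stop("`precip` must be >= 0", call. = FALSE)
  s <- svp_slope(temp)
  sec_per_year <- .const$hours_per_year * .const$sec_per_hour
  pet <- pmax(0, s / (s + .const$gamma_psy) * net_radiation) /
    .const$lambda_vap * sec_per_year  # kg m-2 yr-1 = mm yr-1
  phi <- ifelse(precip > 0, pet / precip, 0)
  evap_frac <- ifelse(phi > 0,
                      sqrt(phi * tanh(1 / phi) * (1 - exp(-phi))), 0)
  runoff <- precip * (1 - pmin(1, evap_frac))
  pmax(0, runoff)
}

#' Relative GEM-CO2 lithology slopes
#'
#' Relative weathering intensity per unit runoff for the six lithology
#' classes (carbonates far above silicates; basalt the most reactive
#' silicate). These are relative weights: [calibrate_gem_slopes()] scales
#' them so a present-day reference runoff field reproduces configured
#' silicate and carbonate calcium fluxes.
#'
#' @return named numeric vector (relative mol Ca per L of runoff).
#' @export
gem_co2_relative_slopes <- function() {
  c(sandstone = 0.15, limestone = 1.60, shale = 0.63,
    granite = 0.22, rhyolite = 0.22, basalt = 0.48)
}

.gem_carbonate_classes <- "limestone"

#' Calibrate GEM-CO2 slopes against present-day component fluxes
#'
#' Scales the relative lithology slopes so that the given runoff field
#' yields the configured present-day silicate and carbonate calcium
#' fluxes (defaults 3.4e12 and 2.1e12 mol Ca yr-1).
#'
#' @param runoff runoff field (mm yr-1).
#' @param grid a `grid_spec`.
#' @param mask logical field of cells contributing (e.g. land).
#' @param fractions lithology fractions (sum to 1).
#' @param silicate_flux,carbonate_flux target fluxes (mol Ca yr-1).
#' @return named numeric vector of calibrated slopes (mol Ca per L).
#' @export
calibrate_gem_slopes <- function(runoff, grid, mask,
                                 fractions = rock_geochem()$lithology_fractions,
                                 silicate_flux = 3.4e12,
                                 carbonate_flux = 2.1e12) {
  rel <- gem_co2_relative_slopes()
  runoff_sum <- area_sum(runoff, grid, mask)  # mm yr-1 * m^2 = L yr-1
  is_carb <- names(rel) %in% .gem_carbonate_classes
  carb_raw <- runoff_sum * sum(fractions[names(rel)[is_carb]] * rel[is_carb])
  sil_raw <- runoff_sum * sum(fractions[names(rel)[!is_carb]] * rel[!is_carb])
  rel[is_carb] <- rel[is_carb] * carbonate_flux / carb_raw
  rel[!is_carb] <- rel[!is_carb] * silicate_flux / sil_raw
  rel
}

#' GEM-CO2 weathering flux from a runoff field
#'
#' Chemical weathering as a linear function of runoff per lithology
#' class: per-cell flux density `runoff * sum_i fraction_i * slope_i`,
#' integrated over the area; totals are split into silicate and carbonate
#' contributions.
#'
#' @param runoff runoff field (mm yr-1 = L m-2 yr-1).
#' @param grid a `grid_spec`.
#' @param mask logical field of contributing cells.
#' @param slopes slopes (mol Ca per L), e.g. from
#'   [calibrate_gem_slopes()].
#' @param fractions lithology fractions (must sum to 1).
#' @return list with `total`, `silicate`, `carbonate` (mol Ca yr-1).
#' @export
gem_co2_flux <- function(runoff, grid, mask,
                         slopes = gem_co2_relative_slopes(),
                         fractions = rock_geochem()$lithology_fractions) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("lithology fractions must sum to 1", call. = FALSE)
  }
  runoff_sum <- area_sum(runoff, grid, mask)
  is_carb <- names(slopes) %in% .gem_carbonate_classes
  carb <- runoff_sum * sum(fractions[names(slopes)[is_carb]] * slopes[is_carb])
  sil <- runoff_sum * sum(fractions[names(slopes)[!is_carb]] * slopes[!is_carb])
  list(total = sil + carb, silicate = sil, carbonate = carb)
}

#' Rescale an estimate by the GEM-CO2 / limit-based present-day ratio
#'
#' The limit-based approach gives a larger present-day weathering flux
#' than GEM-CO2 (clay formation and kinetic limitation); scaling an
#' estimate by the ratio of the two present-day values transfers that
#' correction: `value * gem_today / limit_today`.
#'
#' @param value estimate to rescale (e.g. km^3 yr-1).
#' @param gem_today,limit_today present-day global weathering from the
#'   two approaches (same units; defaults 1.3 and 1.8 km^3 yr-1).
#' @return the rescaled value.
#' @export
gem_rescale <- function(value, gem_today = 1.3, limit_today = 1.8) {
  value * gem_today / limit_today
}

#' GEOCARB-style configuration
#'
#' Standard GEOCARB III forms: silicate weathering scales as
#' `exp(act * dT) * (1 + run_coef * dT)^run_exp` and carbonate weathering
#' as `1 + carb_coef * dT`, both times an abiotic CO2 kinetic factor
#' `(co2_pal)^co2_exp`, an uplift factor, a land-area factor, and the
#' pre-vascular biotic factor 0.25.
#'
#' @param f_biotic_prevascular weathering fraction without vascular
#'   plants (default 0.25).
#' @param f_uplift,f_land_area dimensionless scalings (defaults 0.9, 1).
#' @param act silicate temperature activation coefficient (K-1).
#' @param run_coef,run_exp silicate runoff-from-temperature response.
#' @param carb_coef carbonate temperature/runoff coefficient (K-1).
#' @param co2_exp abiotic CO2 kinetic exponent (0.5).
#' @param t0 present-day reference land temperature (degC).
#' @param present_day_silicate_flux,present_day_carbonate_flux mol Ca
#'   yr-1 (defaults 3.4e12 and 2.1e12).
#' @return list of class `geocarb_config`.
#' @export
geocarb_config <- function(f_biotic_prevascular = 0.25,
                           f_uplift = 0.9, f_land_area = 1,
                           act = 0.09, run_coef = 0.038, run_exp = 0.65,
                           carb_coef = 0.087, co2_exp = 0.5, t0 = 14,
                           present_day_silicate_flux = 3.4e12,
                           present_day_carbonate_flux = 2.1e12) {
  if (f_biotic_prevascular <= 0 || f_biotic_prevascular > 1) {
    stop("`f_biotic_prevascular` must be in (0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "geocarb_config")
}

#' Abiotic Ordovician weathering by GEOCARB-style scaling
#'
#' Scales the present-day silicate and carbonate calcium fluxes to the
#' Ordovician using the temperature/runoff/CO2 factors, uplift, land
#' area and the pre-vascular biotic factor, then converts to a rock
#' volume. The land temperature is supplied externally (here from the
#' synthetic climate) so that biotic and abiotic estimates share the same
#' forcing.
#'
#' @param land_temp mean land surface temperature (degC).
#' @param co2_pal atmospheric CO2 (PAL, > 0).
#' @param cfg a [geocarb_config()].
#' @param rock a [rock_geochem()] for the calcium-to-volume conversion.
#' @return abiotic weathering (km^3 rock yr-1).
#' @export
geocarb_abiotic <- function(land_temp, co2_pal, cfg = geocarb_config(),
                            rock = rock_geochem()) {
  assert_positive(co2_pal)
  dt <- land_temp - cfg$t0
  f_sil <- exp(cfg$act * dt) * pmax(0, 1 + cfg$run_coef * dt)^cfg$run_exp
  f_carb <- pmax(0, 1 + cfg$carb_coef * dt)
  f_co2 <- co2_pal^cfg$co2_exp
  flux <- (cfg$present_day_silicate_flux * f_sil +
             cfg$present_day_carbonate_flux * f_carb) *
    f_co2 * cfg$f_uplift * cfg$f_land_area * cfg$f_biotic_prevascular
  ca_flux_to_rock_volume(flux, rock)
}
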