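# Open-system carbonate equilibrium: the maximum dissolved calcium in soil
# water in contact with a CO2 reservoir at fixed partial pressure, capped
# by calcite solubility. Solved from the full speciation charge balance.

# Equilibrium constants at 25 degC (mol/L, atm).
.carb_k <- list(
  kh  = 10^-1.468,   # CO2(g) <-> H2CO3*
  k1  = 10^-6.352,   # H2CO3* <-> H+ + HCO3-
  k2  = 10^-10.329,  # HCO3-  <-> H+ + CO3--
  ksp = 10^-8.48,    # CaCO3  <-> Ca++ + CO3--
  kw  = 10^-14
)

#' Soil-chemistry settings for the runoff weathering limit
#'
#' @param soil_pco2_ppm soil CO2 partial pressure (ppm; default 10000, a
#'   typical modern value at intermediate soil depth). It should not fall
#'   below the atmospheric CO2 concentration.
#' @param temperature soil temperature (degC); recorded with the settings,
#'   the equilibrium constants are evaluated at 25 degC.
#' @param composition_factor relative activity of calcium-bearing minerals
#'   in the regolith (1 = the mean-lithology reference; 0 = no Ca-bearing
#'   minerals).
#' @return list of class `soil_chemistry`.
#' @export
soil_chemistry <- function(soil_pco2_ppm = 10000, temperature = 15,
                           composition_factor = 1) {
  assert_positive(soil_pco2_ppm)
  if (composition_factor < 0) stop("`composition_factor` must be >= 0", call. = FALSE)
  structure(list(soil_pco2_ppm = soil_pco2_ppm, temperature = temperature,
                 composition_factor = composition_factor),
            class = "soil_chemistry")
}

#' Equilibrium calcium concentration with respect to calcite
#'
#' Solves the open-system speciation (CO2 dissolution, two carbonic-acid
#' dissociations, calcite solubility, water autoionisation) with the charge
#' balance `2[Ca] + [H] = [HCO3] + 2[CO3] + [OH]`, where the calcite term
#' is scaled by the regolith composition factor. The proton activity is
#' found by bisection in log space to ~1e-10 relative precision. In the
#' ideal dilute limit the solution follows the cube-root law
#' `[Ca] ~ pCO2^(1/3)`.
#'
#' @param soil a [soil_chemistry()].
#' @return dissolved calcium at equilibrium (mol per m^3 of water).
#' @export
calcite_equilibrium_ca <- function(soil = soil_chemistry()) {
  if (!inherits(soil, "soil_chemistry")) soil <- do.call(soil_chemistry, soil)
  p_atm <- soil$soil_pco2_ppm * 1e-6
  f <- soil$composition_factor
  if (f == 0) return(0)
  k <- .carb_k
  c1 <- k$kh * p_atm * k$k1          # [HCO3][H]
  c2 <- c1 * k$k2                    # [CO3][H]^2
  ca_of_h <- function(h) f * k$ksp * h^2 / c2
  balance <- function(h) {
    2 * ca_of_h(h) + h - (c1 / h + 2 * c2 / h^2 + k$kw / h)
  }
  lo <- log(1e-14); hi <- log(1e-1)
  if (balance(exp(lo)) > 0 || balance(exp(hi)) < 0) {
    stop("carbonate equilibrium: no root in bracket", call. = FALSE)
  }
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (balance(exp(mid)) < 0) lo <- mid else hi <- mid
  }
  h <- exp((lo + hi) / 2)
  1000 * ca_of_h(h)   # mol/L -> mol/m3
}
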