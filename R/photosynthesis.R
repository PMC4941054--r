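# Farquhar photosynthesis with a carbon-concentration mechanism (CCM),
# Q10 respiration, and the water-content control of thallus CO2 diffusion.
# Rates are umol CO2 m-2 s-1; CO2 concentrations are ppm (umol/mol); O2 is
# a mole fraction.

# Arrhenius response normalised to 25 degC.
arrhenius <- function(temp_c, k25, ea) {
  k25 * exp(ea * (temp_c - 25) / (8.314 * 298.15 * (temp_c + 273.15)))
}

# Kinetic constants (Bernacchi-type temperature responses). The CO2
# compensation point scales linearly with O2 (photorespiration); the
# reference value is defined at 21% O2.
farquhar_kinetics <- function(temp_c, o2) {
  gamma_star <- arrhenius(temp_c, 42.75, 37830) * o2 / 0.21  # ppm
  kc <- arrhenius(temp_c, 404.9, 79430)                      # ppm
  ko <- arrhenius(temp_c, 278.4, 36380)                      # mmol/mol
  list(gamma_star = gamma_star,
       kc_eff = kc * (1 + 1000 * o2 / ko))                   # ppm
}

# Capacity (Vcmax, Jmax) temperature response: Q10-like kinetic rise
# (matching the scale of the respiratory Q10, so the capacity-to-
# respiration ratio is roughly temperature-neutral below the optimum)
# with Gaussian heat deactivation above the species' t_opt. Equal to 1
# at the 20 degC reference for heat-tolerant species.
capacity_factor <- function(temp_c, t_opt, q10_kinetic = 2,
                            deactivation_width = 8) {
  q10_kinetic^((temp_c - 20) / 10) *
    exp(-(pmax(0, temp_c - t_opt) / deactivation_width)^2)
}

# Electron transport from incident PAR (umol photons m-2 s-1), saturating
# Michaelis form; alpha is the effective quantum yield of electron
# transport on an incident-light basis.
electron_transport <- function(par, jmax_t, alpha = 0.3) {
  alpha * par * jmax_t / (alpha * par + jmax_t)
}

# Core gross-assimilation law given precomputed temperature terms.
# cc: CO2 at the carboxylation site (ppm); j_eff: CCM-debited electron flux.
.farquhar_A <- function(cc, gamma_star, kc_eff, vcmax_t, j_eff) {
  wc <- vcmax_t * (cc - gamma_star) / (cc + kc_eff)
  wj <- (j_eff / 4) * (cc - gamma_star) / (cc + 2 * gamma_star)
  pmax(0, pmin(wc, wj))
}

#' Gross assimilation by the Farquhar scheme with a CCM
#'
#' The gross rate is the minimum of the carboxylation-limited rate
#' `Wc = Vcmax (Cc - G*) / (Cc + Kc (1 + O/Ko))` and the light-limited
#' rate `Wj = (J/4) (Cc - G*) / (Cc + 2 G*)`, clipped at zero. The CCM
#' raises CO2 at the carboxylation site to `Cc = eta_ccm * ci` at an
#' electron cost debited from the light reactions,
#' `J_eff = J / (1 + ccm_cost (eta_ccm - 1))`. Kinetic constants follow
#' Arrhenius temperature responses; capacities use a Gaussian optimum at
#' the species' `t_opt`, normalised at the 20 degC reference.
#'
#' @param params one species (single row of a `species_params`, or list
#'   with the same fields).
#' @param par incident photosynthetically active radiation
#'   (umol photons m-2 s-1).
#' @param temp temperature (degC).
#' @param ci thallus-internal CO2 (ppm).
#' @param o2 ambient O2 mole fraction (default 0.21).
#' @param alpha quantum yield of electron transport (incident basis).
#' @param ccm_cost electron cost per unit of CCM concentration factor.
#' @return gross assimilation (umol CO2 m-2 s-1), vectorised over `par`,
#'   `temp` and `ci`.
#' @export
farquhar_gpp <- function(params, par, temp, ci, o2 = 0.21,
                         alpha = 0.3, ccm_cost = 0.02) {
  if (any(par < 0) || any(ci < 0) || any(o2 < 0)) {
    stop("`par`, `ci` and `o2` must be non-negative", call. = FALSE)
  }
  kin <- farquhar_kinetics(temp, o2)
  f <- capacity_factor(temp, params$t_opt)
  j <- electron_transport(par, params$jmax_ref * f, alpha)
  j_eff <- j / (1 + ccm_cost * (params$eta_ccm - 1))
  .farquhar_A(params$eta_ccm * ci, kin$gamma_star, kin$kc_eff,
              params$vcmax_ref * f, j_eff)
}

#' Maintenance respiration (Q10 law)
#'
#' `R = resp_ref * q10^((temp - 20)/10)`, with the reference rate tied to
#' photosynthetic capacity through `resp_ref = vcmax_ref / phi_rr`.
#'
#' @inheritParams farquhar_gpp
#' @param temp temperature (degC), vectorised.
#' @return respiration (umol CO2 m-2 s-1).
#' @export
respiration <- function(params, temp) {
  params$resp_ref * params$q10^((temp - 20) / 10)
}

#' Thallus CO2 diffusivity as a function of water saturation
#'
#' Diffusivity decreases monotonically with water content: a water-filled
#' thallus impedes gaseous CO2 transport. `D(1) = d_co2_sat` (the sampled
#' per-species value at full saturation) and the dry thallus is
#' `dry_factor` times more permeable; the transition follows
#' `D(s) = d_co2_sat (1 + (dry_factor - 1) (1 - s)^exponent)`
#' (a linear-to-power-law family).
#'
#' @inheritParams farquhar_gpp
#' @param saturation water content as a fraction of storage capacity, in
#'   `[0, 1]`.
#' @param dry_factor ratio of dry to saturated diffusivity (default 10).
#' @param exponent shape of the decrease (1 = linear, default).
#' @return diffusivity (m s-1).
#' @export
co2_diffusivity <- function(params, saturation, dry_factor = 10, exponent = 1) {
  if (any(saturation < 0 | saturation > 1)) {
    stop("`saturation` must be in [0, 1]", call. = FALSE)
  }
  params$d_co2_sat * (1 + (dry_factor - 1) * (1 - saturation)^exponent)
}

#' Thallus-internal CO2 from the supply-demand balance
#'
#' Balances diffusive CO2 supply `g (ca - ci)` against assimilation
#' demand, where the conductance `g` follows from [co2_diffusivity()].
#' With a constant demand the balance is closed-form
#' (`ci = ca - demand/g`, floored at zero); with a demand function of
#' `ci` (e.g. the Farquhar rate) the consistent `(ci, A)` pair is found
#' by bisection to a relative tolerance of 1e-9.
#'
#' @inheritParams co2_diffusivity
#' @param ambient_co2 ambient CO2 (ppm).
#' @param demand either a single non-negative rate (umol CO2 m-2 s-1) or
#'   a function `A(ci)` that is non-decreasing in `ci`.
#' @param ... passed to [co2_diffusivity()].
#' @return list with `ci` (ppm) and `A` (the demand at `ci`).
#' @export
internal_co2 <- function(params, saturation, ambient_co2, demand, ...) {
  d <- co2_diffusivity(params, saturation, ...)
  g <- d * .const$mol_air  # umol m-2 s-1 per ppm
  if (is.function(demand)) {
    lo <- 0
    hi <- ambient_co2
    if (ambient_co2 <= 0) return(list(ci = 0, A = max(0, demand(0))))
    for (iter in 1:80) {
      mid <- (lo + hi) / 2
      if (g * (ambient_co2 - mid) - demand(mid) > 0) lo <- mid else hi <- mid
      if ((hi - lo) <= 1e-9 * ambient_co2) break
    }
    ci <- (lo + hi) / 2
    list(ci = ci, A = demand(ci))
  } else {
    if (any(demand < 0)) stop("`demand` must be non-negative", call. = FALSE)
    ci <- pmax(0, ambient_co2 - demand / g)
    list(ci = ci, A = demand)
  }
}

#' Coupled net photosynthesis of one species
#'
#' Solves the diffusive supply / Farquhar demand balance for the internal
#' CO2 and returns gross assimilation, respiration and their difference.
#' This is the steady-state rate used hour-by-hour in the simulation and
#' for the CO2/light/O2 response curves (constant conditions).
#'
#' @inheritParams farquhar_gpp
#' @inheritParams co2_diffusivity
#' @param co2_ppm ambient CO2 (ppm).
#' @return list of vectors `A` (gross, umol m-2 s-1), `resp`, `npp`
#'   (= A - resp) and `ci` (ppm), vectorised over `par`, `temp`,
#'   `saturation`.
#' @export
photosynthesis_rate <- function(params, par, temp, saturation, co2_ppm,
                                o2 = 0.21, alpha = 0.3, ccm_cost = 0.02,
                                dry_factor = 10, exponent = 1) {
  n <- max(length(par), length(temp), length(saturation))
  par <- rep_len(par, n); temp <- rep_len(temp, n)
  saturation <- rep_len(saturation, n)

  kin <- farquhar_kinetics(temp, o2)
  f <- capacity_factor(temp, params$t_opt)
  vc_t <- params$vcmax_ref * f
  j_eff <- electron_transport(par, params$jmax_ref * f, alpha) /
    (1 + ccm_cost * (params$eta_ccm - 1))
  g <- co2_diffusivity(params, saturation, dry_factor, exponent) * .const$mol_air

  lo <- rep(0, n)
  hi <- rep(co2_ppm, n)
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    a_mid <- .farquhar_A(params$eta_ccm * mid, kin$gamma_star, kin$kc_eff,
                         vc_t, j_eff)
    up <- g * (co2_ppm - mid) - a_mid > 0
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
  }
  ci <- (lo + hi) / 2
  A <- .farquhar_A(params$eta_ccm * ci, kin$gamma_star, kin$kc_eff, vc_t, j_eff)
  r <- respiration(params, temp)
  list(A = A, resp = r, npp = A - r, ci = ci)
}
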