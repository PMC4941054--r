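# Monte-Carlo sampling of artificial species. Each species is a vector of
# physiological parameters drawn from observed trait ranges; the sampled
# species stand in for the physiological diversity of real lichens and
# bryophytes rather than for particular taxa.

#' Default trait sampling ranges for artificial species
#'
#' The ranges are package choices representative of published lichen and
#' bryophyte physiology: low photosynthetic capacities compared with
#' vascular leaves, thallus CO2 diffusivities spanning more than an order
#' of magnitude, and water-storage capacities of a few kilograms per
#' square metre. Rate constants are sampled log-uniformly, shape and
#' storage parameters uniformly.
#'
#' @return data.frame with columns `param`, `min`, `max`, `log`.
#' @export
default_species_ranges <- function() {
  data.frame(
    param = c("vcmax_ref", "jmax_ratio", "q10", "d_co2_sat",
              "theta_max", "albedo", "t_opt"),
    min   = c(1.5,  1.5, 1.8, 3e-5, 1.0, 0.08,  5),
    max   = c(18,   2.5, 2.5, 1e-3, 8.0, 0.30, 35),
    log   = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Rescale the thallus CO2 diffusivity sampling range
#'
#' Helper for the trait-range sensitivity scenarios: extend the sampled
#' diffusivity range by scaling its lower and/or upper end (e.g.
#' `high = 2` doubles the maximum, `low = 0.5` halves the minimum).
#'
#' @param ranges a ranges table as from [default_species_ranges()].
#' @param low,high multipliers for the minimum and maximum of `d_co2_sat`.
#' @return the modified ranges table.
#' @export
scale_dco2_range <- function(ranges, low = 1, high = 1) {
  k <- ranges$param == "d_co2_sat"
  ranges$min[k] <- ranges$min[k] * low
  ranges$max[k] <- ranges$max[k] * high
  ranges
}

#' Sample artificial species by Monte Carlo
#'
#' Draws `n` independent parameter vectors from the trait ranges. The ratio
#' of Rubisco content to maintenance respiration (`phi_rr`) and the
#' carbon-concentration-mechanism factor (`eta_ccm`) are universal
#' physiological constraints and therefore identical across all species of
#' one simulation; reference respiration is tied to photosynthetic
#' capacity via `resp_ref = vcmax_ref / phi_rr`.
#'
#' @param n number of species (>= 1).
#' @param seed integer seed; sampling is deterministic given the seed.
#' @param ranges trait ranges table ([default_species_ranges()]).
#' @param phi_rr ratio of Rubisco content (photosynthetic capacity, via
#'   `vcmax_ref`) to maintenance respiration at the 20 degC reference
#'   (dimensionless, default 15).
#' @param eta_ccm CCM concentration factor: internal CO2 at the
#'   carboxylation site is `eta_ccm` times the thallus-internal CO2
#'   (default 8; theoretical upper end 45).
#' @return object of class `species_params` (a data.frame, one row per
#'   species) with columns `vcmax_ref`, `jmax_ref` (umol m-2 s-1 at 20
#'   degC), `q10`, `resp_ref` (umol m-2 s-1 at 20 degC), `phi_rr`,
#'   `d_co2_sat` (m s-1 at full saturation), `eta_ccm`, `theta_max`
#'   (kg H2O m-2), `albedo`, `t_opt` (degC).
#' @export
sample_species <- function(n, seed, ranges = default_species_ranges(),
                           phi_rr = 15, eta_ccm = 8) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (any(!is.finite(ranges$min)) || any(!is.finite(ranges$max)) ||
      any(ranges$min > ranges$max) || any(ranges$min <= 0 & ranges$log)) {
    stop("invalid sampling ranges", call. = FALSE)
  }
  assert_positive(phi_rr)
  assert_positive(eta_ccm)
  n <- as.integer(n)
  draws <- withr::with_seed(derive_seed(seed, 404L), {
    out <- lapply(seq_len(nrow(ranges)), function(k) {
      lo <- ranges$min[k]; hi <- ranges$max[k]
      if (ranges$log[k]) {
        exp(stats::runif(n, log(lo), log(hi)))
      } else {
        stats::runif(n, lo, hi)
      }
    })
    names(out) <- ranges$param
    out
  })
  sp <- data.frame(
    vcmax_ref = draws$vcmax_ref,
    jmax_ref  = draws$vcmax_ref * draws$jmax_ratio,
    q10       = draws$q10,
    resp_ref  = draws$vcmax_ref / phi_rr,
    phi_rr    = phi_rr,
    d_co2_sat = draws$d_co2_sat,
    eta_ccm   = eta_ccm,
    theta_max = draws$theta_max,
    albedo    = draws$albedo,
    t_opt     = draws$t_opt
  )
  class(sp) <- c("species_params", "data.frame")
  sp
}

#' Fixture species parameterisations for liverwort-like response curves
#'
#' Two hand-calibrated parameter vectors, I and II, that differ mainly in
#' photosynthetic capacity. They reproduce a laboratory-grown (I) and an
#' outdoor-grown (II) liverwort anchor of net photosynthesis of about 5 and
#' 2 umol CO2 m-2 s-1 respectively at 400 ppm CO2, 250 umol m-2 s-1 PAR,
#' 21% O2, 20 degC and full water saturation.
#'
#' @return a `species_params` data.frame with rows "I" and "II".
#' @export
fixture_species <- function() {
  sp <- data.frame(
    vcmax_ref = c(30.0, 6.8),
    jmax_ref  = c(60.0, 13.6),
    q10       = c(2.0, 2.0),
    resp_ref  = c(30.0, 6.8) / 15,
    phi_rr    = 15,
    d_co2_sat = c(1.5e-3, 1.5e-3),
    eta_ccm   = 8,
    theta_max = c(4, 4),
    albedo    = 0.15,
    t_opt     = c(20, 20)
  )
  rownames(sp) <- c("I", "II")
  class(sp) <- c("species_params", "data.frame")
  sp
}
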