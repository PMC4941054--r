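# Conversion of NPP into a phosphorus-driven rock-weathering flux, the
# erosion and runoff (calcite-equilibrium) limits, the cell-wise minimum,
# and the phosphorus feedback on NPP. Weathering is expressed as the
# volume of primary minerals chemically transformed per area and time
# (m^3 rock m-2 yr-1, i.e. m yr-1).

#' Phosphorus stoichiometry of non-vascular biomass
#'
#' The C:P mass ratio converts NPP into a phosphorus requirement;
#' resorption from senescing tissue and leaching losses nearly compensate
#' (net factor `1 - resorption_frac + leaching_frac`, equal to 1 at the
#' defaults), and the recycling ratio divides the requirement into the
#' share that must come from fresh rock. The default C:P of 350 g C per
#' g P is calibrated so that a typical lichen-dominated desert (NPP
#' 5 g C m-2 yr-1, surface weathering 0.002 mm yr-1, rock phosphorus
#' 1432 g m-3) implies a recycling ratio of ~5:1.
#'
#' @param cp_mass_ratio g C per g P in biomass (default 350).
#' @param resorption_frac fraction of P recovered from senescing tissue.
#' @param leaching_frac fraction of P lost by leaching.
#' @param recycling_ratio total P uptake per unit of new P from rock
#'   (>= 1; default 5 for pre-vascular ecosystems, ~50 for modern
#'   vascular ones).
#' @return list of class `stoichiometry`.
#' @export
stoichiometry <- function(cp_mass_ratio = 350, resorption_frac = 0.6,
                          leaching_frac = 0.6, recycling_ratio = 5) {
  assert_positive(cp_mass_ratio)
  if (recycling_ratio < 1) stop("`recycling_ratio` must be >= 1", call. = FALSE)
  if (resorption_frac < 0 || resorption_frac > 1 ||
      leaching_frac < 0 || leaching_frac > 1) {
    stop("fractions must be in [0, 1]", call. = FALSE)
  }
  structure(list(cp_mass_ratio = cp_mass_ratio,
                 resorption_frac = resorption_frac,
                 leaching_frac = leaching_frac,
                 recycling_ratio = recycling_ratio),
            class = "stoichiometry")
}

#' Average rock geochemistry
#'
#' Globally uniform rock properties: area-weighted mean phosphorus
#' concentration 1432 g P per m^3 rock, mean density 2500 kg m-3, calcium
#' mass fractions of 40% in calcite and 14% in calcium feldspar, and a
#' global molar calcium concentration calibrated from the pair (7.7e12
#' mol Ca yr-1 <-> 1.8 km^3 rock yr-1), i.e. ~4278 mol Ca per m^3 rock.
#' The lithology mix over the six classes is a synthetic illustrative
#' composition (the layout of real lithology maps, not their values).
#'
#' @param p_conc g P per m^3 rock.
#' @param ca_molar_conc mol Ca per m^3 rock (calibrated constant).
#' @param density kg m-3.
#' @param calcite_ca_frac,ca_feldspar_ca_frac calcium mass fractions.
#' @param lithology_fractions named fractions over sandstone, limestone,
#'   shale, granite, rhyolite, basalt (must sum to 1).
#' @return list of class `rock_geochem`.
#' @export
rock_geochem <- function(p_conc = 1432,
                         ca_molar_conc = 7.7e12 / 1.8e9,
                         density = 2500,
                         calcite_ca_frac = 0.40,
                         ca_feldspar_ca_frac = 0.14,
                         lithology_fractions = c(sandstone = 0.26,
                                                 limestone = 0.16,
                                                 shale = 0.26,
                                                 granite = 0.14,
                                                 rhyolite = 0.08,
                                                 basalt = 0.10)) {
  assert_positive(p_conc)
  assert_positive(density)
  if (abs(sum(lithology_fractions) - 1) > 1e-8) {
    stop("lithology fractions must sum to 1", call. = FALSE)
  }
  structure(list(p_conc = p_conc, ca_molar_conc = ca_molar_conc,
                 density = density, calcite_ca_frac = calcite_ca_frac,
                 ca_feldspar_ca_frac = ca_feldspar_ca_frac,
                 lithology_fractions = lithology_fractions),
            class = "rock_geochem")
}

#' Phosphorus demand from rock implied by an NPP
#'
#' `demand = (npp / cp_mass_ratio) * (1 - resorption + leaching) /
#' recycling_ratio`. With the default stoichiometry the
#' resorption/leaching factor is exactly 1.
#'
#' @param npp net primary productivity (g C m-2 yr-1, >= 0); vectorised.
#' @param stoich a [stoichiometry()].
#' @return phosphorus required from fresh rock (g P m-2 yr-1).
#' @export
phosphorus_demand <- function(npp, stoich = stoichiometry()) {
  if (any(npp < 0, na.rm = TRUE)) stop("`npp` must be >= 0", call. = FALSE)
  (npp / stoich$cp_mass_ratio) *
    (1 - stoich$resorption_frac + stoich$leaching_frac) /
    stoich$recycling_ratio
}

#' NPP-based weathering flux
#'
#' Rock volume that must be dissolved to supply a phosphorus demand:
#' `W = demand / p_conc`.
#'
#' @param p_demand g P m-2 yr-1 (vectorised).
#' @param rock a [rock_geochem()].
#' @return weathering (m^3 rock m-2 yr-1).
#' @export
npp_weathering <- function(p_demand, rock = rock_geochem()) {
  if (any(p_demand < 0, na.rm = TRUE)) stop("`p_demand` must be >= 0", call. = FALSE)
  if (rock$p_conc <= 0) stop("`p_conc` must be positive", call. = FALSE)
  p_demand / rock$p_conc
}

#' Erosion limit on chemical weathering
#'
#' In steady state chemical weathering cannot exceed the exposure rate of
#' fresh rock, which equals the erosion (denudation) rate; erosion is
#' taken proportional to mean surface elevation, `W_ero = k_e * z`. The
#' default constant gives ~0.06 mm yr-1 at 1000 m elevation.
#'
#' @param elevation m above sea level (>= 0); vectorised.
#' @param k_e erosion constant (yr-1).
#' @return maximum weathering (m^3 rock m-2 yr-1).
#' @export
erosion_limit <- function(elevation, k_e = 6e-8) {
  if (any(elevation < 0, na.rm = TRUE)) {
    stop("`elevation` must be >= 0", call. = FALSE)
  }
  k_e * elevation
}

#' Runoff (solute-transport) limit on chemical weathering
#'
#' The export of dissolved weathering products is the product of runoff
#' and the equilibrium soil calcium concentration, divided by the calcium
#' concentration of rocks: `W_run = runoff * ca_eq / ca_molar_conc`. Only
#' runoff from vegetated area should be passed in.
#'
#' @param runoff mm yr-1 (vectorised).
#' @param ca_eq equilibrium dissolved calcium (mol m-3), from
#'   [calcite_equilibrium_ca()].
#' @param rock a [rock_geochem()].
#' @return maximum weathering (m^3 rock m-2 yr-1).
#' @export
runoff_limit <- function(runoff, ca_eq, rock = rock_geochem()) {
  if (any(runoff < 0, na.rm = TRUE)) stop("`runoff` must be >= 0", call. = FALSE)
  (runoff * 1e-3) * ca_eq / rock$ca_molar_conc
}

#' Cell-wise minimum of the three weathering limits
#'
#' Realized weathering is the minimum of the NPP-based flux and the
#' erosion and runoff limits. Ties are labelled with priority
#' npp > erosion > runoff.
#'
#' @param w_npp,w_ero,w_run fields (equal dimensions).
#' @return list with `w_realized` and `limiting_factor` (character array
#'   of "npp", "erosion", "runoff").
#' @export
apply_limits <- function(w_npp, w_ero, w_run) {
  if (!all(dim(w_npp) %||% length(w_npp) == dim(w_ero) %||% length(w_ero)) ||
      !all(dim(w_npp) %||% length(w_npp) == dim(w_run) %||% length(w_run))) {
    stop("limit fields must have identical shapes", call. = FALSE)
  }
  w_realized <- pmin(w_npp, w_ero, w_run)
  lab <- ifelse(w_npp <= pmin(w_ero, w_run), "npp",
                ifelse(w_ero <= w_run, "erosion", "runoff"))
  if (!is.null(dim(w_npp))) {
    lab <- array(lab, dim = dim(w_npp))
    w_realized <- array(w_realized, dim = dim(w_npp))
  }
  list(w_realized = w_realized, limiting_factor = lab)
}

#' Phosphorus-limited (realized) NPP
#'
#' Where erosion or runoff caps weathering below the NPP-based flux, the
#' phosphorus actually supplied is converted back into NPP through the
#' C:P ratio, i.e. potential NPP is scaled by `w_realized / w_npp`
#' (cells with no phosphorus demand are unlimited).
#'
#' @param potential_npp field (g C m-2 yr-1).
#' @param w_npp,w_realized weathering fields with `w_realized <= w_npp`.
#' @return realized NPP field.
#' @export
phosphorus_limited_npp <- function(potential_npp, w_npp, w_realized) {
  if (any(w_realized > w_npp * (1 + 1e-12), na.rm = TRUE)) {
    stop("`w_realized` must not exceed `w_npp`", call. = FALSE)
  }
  ifelse(w_npp > 0, potential_npp * w_realized / w_npp, potential_npp)
}

#' Convert a global calcium flux to a rock volume
#'
#' Uses the calibrated global molar calcium concentration of rock
#' (defaults reproduce 7.7e12 mol yr-1 <-> 1.8 km^3 yr-1).
#'
#' @param flux mol Ca yr-1 (>= 0).
#' @param rock a [rock_geochem()].
#' @return rock volume (km^3 yr-1).
#' @export
ca_flux_to_rock_volume <- function(flux, rock = rock_geochem()) {
  if (any(flux < 0)) stop("`flux` must be >= 0", call. = FALSE)
  flux / rock$ca_molar_conc / 1e9
}

#' Percent reduction between two values
#'
#' @param from,to scalars with `from > 0`.
#' @return `100 * (from - to) / from`.
#' @export
percent_reduction <- function(from, to) {
  assert_positive(from)
  100 * (from - to) / from
}

#' Full weathering computation from vegetation fields
#'
#' Applies the NPP-to-phosphorus-to-rock conversion, the erosion and
#' runoff limits (runoff counts only from the vegetated fraction of each
#' cell), the cell-wise minimum, and the phosphorus feedback on NPP and
#' GPP.
#'
#' @param veg a `veg_fields` from [run_grid()].
#' @param paleo the `paleogeography` used for the run.
#' @param stoich,rock,soil component settings.
#' @param k_e erosion constant, see [erosion_limit()].
#' @return object of class `weathering_result` with fields `w_npp`,
#'   `w_erosion`, `w_runoff`, `w_realized` (m yr-1), `limiting_factor`,
#'   `realized_npp`, `realized_gpp` (g C m-2 yr-1), and `ca_eq`
#'   (mol m-3).
#' @export
weathering_from_veg <- function(veg, paleo,
                                stoich = stoichiometry(),
                                rock = rock_geochem(),
                                soil = soil_chemistry(),
                                k_e = 6e-8) {
  ca_eq <- calcite_equilibrium_ca(soil)
  w_npp <- npp_weathering(phosphorus_demand(veg$potential_npp, stoich), rock)
  w_ero <- erosion_limit(paleo$elevation, k_e)
  w_run <- runoff_limit(veg$runoff * veg$cover, ca_eq, rock)
  lim <- apply_limits(w_npp, w_ero, w_run)
  realized_npp <- phosphorus_limited_npp(veg$potential_npp, w_npp,
                                         lim$w_realized)
  ratio <- ifelse(w_npp > 0, lim$w_realized / w_npp, 1)
  structure(
    list(w_npp = w_npp, w_erosion = w_ero, w_runoff = w_run,
         w_realized = lim$w_realized, limiting_factor = lim$limiting_factor,
         realized_npp = realized_npp, realized_gpp = veg$gpp * ratio,
         ca_eq = ca_eq, grid = veg$grid),
    class = "weathering_result"
  )
}

#' Global area-weighted totals of a simulation
#'
#' Produces the standard summary row: global weathering (km^3 rock yr-1),
#' realized NPP and GPP (Gt C yr-1), mean cover over the available (land,
#' non-glaciated) area, and biomass (Gt C). Weathering and productivity
#' are summed over vegetated cells only.
#'
#' @param wres a `weathering_result`.
#' @param veg the `veg_fields` it was derived from.
#' @param grid the `grid_spec`.
#' @return one-row data.frame with columns `npp_gt`, `gpp_gt`, `cover`,
#'   `biomass_gt`, `weathering_km3`, and the potential (pre-feedback)
#'   columns `potential_npp_gt`, `potential_weathering_km3`.
#' @export
global_totals <- function(wres, veg, grid) {
  m <- veg$vegetated
  data.frame(
    npp_gt = area_sum(wres$realized_npp, grid, m) * 1e-15,
    gpp_gt = area_sum(wres$realized_gpp, grid, m) * 1e-15,
    cover = area_mean(veg$cover, grid, veg$available),
    biomass_gt = area_sum(veg$biomass, grid, m) * 1e-15,
    weathering_km3 = area_sum(wres$w_realized, grid, m) / 1e9,
    potential_npp_gt = area_sum(veg$potential_npp, grid, m) * 1e-15,
    potential_weathering_km3 = area_sum(wres$w_npp, grid, m) / 1e9
  )
}
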