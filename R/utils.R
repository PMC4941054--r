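#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Each stochastic stage (paleogeography, climate noise, weather generator per
#' grid cell, species sampling) draws from its own sub-stream so that results
#' do not depend on evaluation order. The derivation is a small integer hash
#' kept strictly below 2^31.
#'
#' @param seed master seed (single integer).
#' @param ... further integer components identifying the sub-stream
#'   (e.g. a module tag and a cell index).
#' @return a single integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 1103515245 + as.numeric(p) + 12345) %% 2147483647
  }
  as.integer(h)
}

assert_scalar_number <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

assert_positive <- function(x, name = deparse(substitute(x))) {
  assert_scalar_number(x, name)
  if (x <= 0) stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

# Saturation vapour pressure (Pa) over water, Magnus form; temp in deg C.
sat_vapour_pressure <- function(temp_c) {
  611.2 * exp(17.62 * temp_c / (243.12 + temp_c))
}

# Slope of the saturation vapour pressure curve (Pa/K).
svp_slope <- function(temp_c) {
  es <- sat_vapour_pressure(temp_c)
  es * 17.62 * 243.12 / (243.12 + temp_c)^2
}

# Physical constants used across modules.
.const <- list(
  sigma_sb     = 5.670374e-8,   # Stefan-Boltzmann, W m-2 K-4
  lambda_vap   = 2.45e6,        # latent heat of vaporisation, J kg-1
  gamma_psy    = 65,            # psychrometric constant, Pa K-1
  earth_radius = 6.371e6,       # m
  mol_air      = 41.6,          # mol air per m3 at surface conditions
  sec_per_hour = 3600,
  hours_per_year = 8640,        # 360-day model year, hourly step
  g_c_per_mol  = 12.011,        # g C per mol CO2
  co2_ppm_per_pal = 280         # 1 PAL = 280 ppm CO2
)
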