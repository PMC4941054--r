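# Shared fixtures, all generated in code and cached per test session so the
# expensive simulations run once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_grid <- function() cached("grid", make_grid(8, 8))

tiny_paleo <- function() cached("paleo",
  generate_paleogeography(tiny_grid(), 42))

tiny_climate <- function() cached("climate",
  generate_monthly_climate(tiny_paleo(), 8, 42))

# hourly forcing for a warm equatorial land cell of the tiny world
tiny_forcing <- function() cached("forcing",
  downscale_to_hourly(tiny_climate(), 7, i = 3, j = 4))

tiny_species <- function(n = 10, seed = 1) sample_species(n, seed)

# one warm-cell vegetation run
tiny_cell <- function() cached("cell",
  run_cell(tiny_species(), tiny_forcing(),
           veg_config(n_hourly_years = 2, n_years = 50)))

# desk-scale end-to-end run reused by pipeline-level tests
tiny_pipeline <- function() cached("pipeline",
  run_pipeline(11, n_lon = 8, n_lat = 8, n_species = 12,
               cfg = veg_config(n_hourly_years = 1, n_years = 30)))

# test-scale configuration for single-cell experiments
quick_cfg <- function(...) veg_config(n_hourly_years = 1, n_years = 30, ...)

# independent full-speciation oracle for the carbonate equilibrium:
# polynomial root of the charge balance
# 2 f Ksp h^4 / C2 + h^3 - (C1 + Kw) h - 2 C2 = 0, solved with polyroot().
oracle_calcite_ca <- function(pco2_ppm, f = 1) {
  kh <- 10^-1.468; k1 <- 10^-6.352; k2 <- 10^-10.329
  ksp <- 10^-8.48; kw <- 10^-14
  p <- pco2_ppm * 1e-6
  c1 <- kh * p * k1
  c2 <- c1 * k2
  coefs <- c(-2 * c2, -(c1 + kw), 0, 1, 2 * f * ksp / c2)
  roots <- polyroot(coefs)
  h <- Re(roots[abs(Im(roots)) < 1e-12 * Mod(roots) & Re(roots) > 0])
  h <- min(h[h > 0])
  1000 * f * ksp * h^2 / c2
}
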