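# Named experiments: end-to-end pipeline runs (climate -> vegetation ->
# weathering -> totals) reproducing the study designs at desk scale, plus
# single-species CO2/light/O2 response curves.

#' Run the full pipeline once
#'
#' Generates paleogeography and monthly climate, samples the species pool,
#' runs the vegetation model over the grid, applies the weathering limits
#' and the phosphorus feedback, and aggregates global totals.
#'
#' @param seed master seed; all stages draw from sub-streams of it.
#' @param n_lon,n_lat grid size.
#' @param co2_pal atmospheric CO2 (PAL).
#' @param scenario paleogeography scenario label.
#' @param n_species initial number of artificial species.
#' @param species optional pre-sampled `species_params` pool (overrides
#'   `n_species`).
#' @param cfg a [veg_config()]; its `co2_pal` is overridden by the
#'   `co2_pal` argument.
#' @param stoich,rock,soil weathering settings.
#' @param k_e erosion constant.
#' @param phi_rr,eta_ccm,ranges species-sampling settings.
#' @param land_fraction land fraction of the paleogeography.
#' @return list with `paleo`, `climate`, `species`, `veg`, `weathering`,
#'   `totals` (one-row data.frame) and `land_temp` (area-weighted annual
#'   mean land temperature, degC).
#' @export
run_pipeline <- function(seed, n_lon = 48, n_lat = 24, co2_pal = 8,
                         scenario = "baseline", n_species = 30,
                         species = NULL, cfg = veg_config(),
                         stoich = stoichiometry(), rock = rock_geochem(),
                         soil = soil_chemistry(), k_e = 6e-8,
                         phi_rr = 15, eta_ccm = 8,
                         ranges = default_species_ranges(),
                         land_fraction = 0.25) {
  grid <- make_grid(n_lon, n_lat)
  paleo <- generate_paleogeography(grid, seed, scenario,
                                   land_fraction = land_fraction)
  climate <- generate_monthly_climate(paleo, co2_pal, seed)
  if (is.null(species)) {
    species <- sample_species(n_species, seed, ranges = ranges,
                              phi_rr = phi_rr, eta_ccm = eta_ccm)
  }
  cfg$co2_pal <- co2_pal
  veg <- run_grid(paleo, climate, species, seed, cfg)
  wres <- weathering_from_veg(veg, paleo, stoich, rock, soil, k_e)
  totals <- global_totals(wres, veg, grid)
  t_ann <- apply(climate$temp, c(1, 2), mean)
  land_temp <- area_mean(t_ann, grid, paleo$land_mask)
  list(paleo = paleo, climate = climate, species = species, veg = veg,
       weathering = wres, totals = totals, land_temp = land_temp)
}

#' Experiment configuration
#'
#' @param name one of `baseline`, `co2_sweep`, `species_sweep`,
#'   `hirnantian`, `param_sensitivity`, `today_reference`,
#'   `response_curves`.
#' @param seed master seed, recorded in the manifest.
#' @param overrides named list overriding experiment defaults (e.g.
#'   `n_lon`, `n_lat`, `n_species`, `n_years`, `co2_levels`,
#'   `species_levels`).
#' @param output_dir directory for CSV outputs and the manifest
#'   (`NULL` = return results only).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(name, seed = 1, overrides = list(),
                              output_dir = NULL) {
  known <- c("baseline", "co2_sweep", "species_sweep", "hirnantian",
             "param_sensitivity", "today_reference", "response_curves")
  if (!name %in% known) {
    stop(sprintf("unknown experiment '%s'", name), call. = FALSE)
  }
  structure(list(name = name, seed = seed, overrides = overrides,
                 output_dir = output_dir),
            class = "experiment_config")
}

# defaults shared by all experiments (desk scale)
.experiment_defaults <- function() {
  list(n_lon = 48, n_lat = 24, n_species = 30, n_years = 50,
       co2_pal = 8, scenario = "baseline", land_fraction = 0.25,
       recycling_ratio = 5, soil_pco2_ppm = 10000, k_e = 6e-8,
       phi_rr = 15, eta_ccm = 8, npp_scale = 1, tau_d_years = 100,
       co2_levels = c(3, 4, 6, 8, 10, 12, 16, 24),
       species_levels = c(10, 30, 100, 300),
       o2 = 0.14)
}

.pipeline_from_opts <- function(seed, o, species = NULL, ranges = NULL,
                                scenario = NULL) {
  cfg <- veg_config(o2 = o$o2, n_years = o$n_years,
                    tau_d_years = o$tau_d_years, npp_scale = o$npp_scale)
  run_pipeline(
    seed, n_lon = o$n_lon, n_lat = o$n_lat, co2_pal = o$co2_pal,
    scenario = scenario %||% o$scenario, n_species = o$n_species,
    species = species, cfg = cfg,
    stoich = stoichiometry(recycling_ratio = o$recycling_ratio),
    soil = soil_chemistry(soil_pco2_ppm = o$soil_pco2_ppm),
    k_e = o$k_e, phi_rr = o$phi_rr, eta_ccm = o$eta_ccm,
    ranges = ranges %||% default_species_ranges(),
    land_fraction = o$land_fraction)
}

.summary_row <- function(scenario, totals) {
  cbind(data.frame(scenario = scenario), totals)
}

#' Run a named experiment
#'
#' Executes the pipeline end-to-end for one of the named designs and
#' returns (and optionally writes) a summary table:
#' \describe{
#'   \item{baseline / hirnantian}{one run at 8 PAL (with or without the
#'     prescribed ice sheet south of 30 deg S).}
#'   \item{co2_sweep}{runs across CO2 levels, with the GEOCARB-style
#'     abiotic weathering computed at each level from the same land
#'     temperature.}
#'   \item{species_sweep}{runs with nested species pools of increasing
#'     size (paired seeds).}
#'   \item{param_sensitivity}{the eight trait-parameter scenarios
#'     (phi_RR x2 and x1/2, diffusivity range extended high/low, eta_CCM
#'     2 and 45, disturbance interval 10 and 250 yr) plus the baseline.}
#'   \item{today_reference}{present-day-like conditions: Budyko runoff
#'     from the synthetic climate, the limit-based global flux, the
#'     calibrated GEM-CO2 flux, and a vegetation run at modern CO2/O2
#'     with recycling ratio 50.}
#'   \item{response_curves}{CO2/light/O2 response curves for the fixture
#'     species and for run-dominant species.}
#' }
#'
#' @param cfg an [experiment_config()].
#' @return list with `summary` (data.frame), `results` (experiment
#'   specific), and `manifest`.
#' @export
run_experiment <- function(cfg) {
  if (!inherits(cfg, "experiment_config")) {
    stop("`cfg` must be an experiment_config", call. = FALSE)
  }
  o <- utils::modifyList(.experiment_defaults(), cfg$overrides)
  seed <- cfg$seed
  results <- list()

  if (cfg$name %in% c("baseline", "hirnantian")) {
    scen <- if (cfg$name == "hirnantian") "hirnantian_ice" else "baseline"
    run <- .pipeline_from_opts(seed, o, scenario = scen)
    summary <- .summary_row(cfg$name, run$totals)
    results$run <- run
  } else if (cfg$name == "co2_sweep") {
    rows <- list()
    for (lev in o$co2_levels) {
      o_lev <- o; o_lev$co2_pal <- lev
      run <- .pipeline_from_opts(seed, o_lev)
      abiotic <- geocarb_abiotic(run$land_temp, lev)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(scenario = sprintf("co2_%g_pal", lev), co2_pal = lev,
                   land_temp = run$land_temp,
                   abiotic_km3 = abiotic),
        run$totals)
    }
    summary <- do.call(rbind, rows)
  } else if (cfg$name == "species_sweep") {
    pool <- sample_species(max(o$species_levels), seed,
                           phi_rr = o$phi_rr, eta_ccm = o$eta_ccm)
    rows <- list()
    for (n in o$species_levels) {
      run <- .pipeline_from_opts(seed, o, species = pool[seq_len(n), ])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(scenario = sprintf("n_species_%d", n), n_species = n),
        run$totals)
    }
    summary <- do.call(rbind, rows)
  } else if (cfg$name == "param_sensitivity") {
    scen <- list(
      baseline    = list(),
      phi_rr_high = list(phi_rr = o$phi_rr * 2),
      phi_rr_low  = list(phi_rr = o$phi_rr / 2),
      d_high      = list(d_high = 2),
      d_low       = list(d_low = 0.5),
      eta_low     = list(eta_ccm = 2),
      eta_high    = list(eta_ccm = 45),
      tau_10      = list(tau_d_years = 10L),
      tau_250     = list(tau_d_years = 250L)
    )
    rows <- list()
    for (nm in names(scen)) {
      o_s <- utils::modifyList(o, scen[[nm]][!names(scen[[nm]]) %in%
                                               c("d_high", "d_low")])
      ranges <- scale_dco2_range(default_species_ranges(),
                                 low = scen[[nm]]$d_low %||% 1,
                                 high = scen[[nm]]$d_high %||% 1)
      run <- .pipeline_from_opts(seed, o_s, ranges = ranges)
      rows[[length(rows) + 1L]] <- .summary_row(nm, run$totals)
    }
    summary <- do.call(rbind, rows)
  } else if (cfg$name == "today_reference") {
    o_t <- utils::modifyList(
      o, list(co2_pal = 360 / 280, o2 = 0.21, recycling_ratio = 50))
    run <- .pipeline_from_opts(seed, o_t)
    grid <- run$paleo$grid
    land <- run$paleo$land_mask
    precip <- apply(run$climate$rain + run$climate$snow, c(1, 2), sum)
    t_ann <- apply(run$climate$temp, c(1, 2), mean)
    sw_ann <- apply(run$climate$sw, c(1, 2), mean)
    lw_ann <- apply(run$climate$lw, c(1, 2), mean)
    rn <- pmax(0, 0.85 * sw_ann + lw_ann -
                 .const$sigma_sb * (t_ann + 273.15)^4)
    runoff <- budyko_runoff(precip, rn, t_ann)
    rock <- rock_geochem()
    ca_eq <- calcite_equilibrium_ca(soil_chemistry(o$soil_pco2_ppm))
    # limit-based present-day flux: min of runoff- and erosion-supported
    runoff_ca <- area_sum(runoff * 1e-3 * ca_eq, grid, land)
    ero_ca <- area_sum(erosion_limit(run$paleo$elevation, o$k_e), grid,
                       land) * rock$ca_molar_conc
    limit_ca <- min(runoff_ca, ero_ca)
    slopes <- calibrate_gem_slopes(runoff, grid, land)
    gem <- gem_co2_flux(runoff, grid, land, slopes)
    results$today <- list(
      runoff = runoff, potential_ca_flux = runoff_ca,
      erosion_ca_flux = ero_ca, limit_ca_flux = limit_ca,
      limit_km3 = ca_flux_to_rock_volume(limit_ca, rock),
      gem = gem, gem_km3 = ca_flux_to_rock_volume(gem$total, rock))
    results$run <- run
    summary <- .summary_row("today_reference", run$totals)
  } else if (cfg$name == "response_curves") {
    summary <- response_curves(fixture_species())
    results$curves <- summary
  }

  manifest <- list(experiment = cfg$name, seed = seed,
                   fingerprint = config_fingerprint(o),
                   options = o)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary,
                     file.path(cfg$output_dir,
                               paste0(cfg$name, "_summary.csv")),
                     row.names = FALSE)
    write_manifest(file.path(cfg$output_dir,
                             paste0(cfg$name, "_manifest.txt")), manifest)
    if (!is.null(results$run)) {
      write_fields_csv(results$run$veg, results$run$weathering,
                       file.path(cfg$output_dir,
                                 paste0(cfg$name, "_fields.csv")))
    }
  }
  list(summary = summary, results = results, manifest = manifest)
}

#' CO2, light and O2 response curves of individual species
#'
#' Net photosynthesis (gross assimilation minus respiration) at constant
#' conditions — full water saturation and 20 degC, the standard protocol —
#' for each species in `species`: versus ambient CO2 (at 250 umol m-2 s-1
#' PAR and 21% O2), versus light (at 400 ppm CO2), and versus O2 (at 400
#' ppm and 250 umol m-2 s-1).
#'
#' @param species a `species_params` table (e.g. [fixture_species()], a
#'   [dominant_species()] row, or several rows bound together). Row names
#'   label the curves.
#' @param co2_range ambient CO2 levels (ppm).
#' @param par_range light levels (umol photons m-2 s-1).
#' @param o2_range O2 mole fractions.
#' @param temp,saturation protocol conditions.
#' @return data.frame with columns `species`, `variable` (co2, light,
#'   o2), `x` and `npp` (umol CO2 m-2 s-1). Zero rows (with a warning)
#'   if `species` is empty.
#' @export
response_curves <- function(species,
                            co2_range = c(100, 200, 400, 700, 1000, 1500,
                                          2240, 3500, 5000, 6720),
                            par_range = c(25, 50, 100, 175, 250, 400, 600,
                                          900, 1200),
                            o2_range = c(0.02, 0.07, 0.14, 0.21, 0.30),
                            temp = 20, saturation = 1) {
  if (is.null(species) || nrow(species) == 0L) {
    warning("no species to evaluate: returning empty result")
    return(data.frame(species = character(), variable = character(),
                      x = numeric(), npp = numeric()))
  }
  labels <- rownames(species) %||% as.character(seq_len(nrow(species)))
  rows <- list()
  for (s in seq_len(nrow(species))) {
    p <- species[s, , drop = FALSE]
    add <- function(variable, x, npp) {
      rows[[length(rows) + 1L]] <<- data.frame(
        species = labels[s], variable = variable, x = x, npp = npp)
    }
    add("co2", co2_range, vapply(co2_range, function(ca)
      photosynthesis_rate(p, 250, temp, saturation, ca, o2 = 0.21)$npp,
      numeric(1)))
    add("light", par_range, vapply(par_range, function(q)
      photosynthesis_rate(p, q, temp, saturation, 400, o2 = 0.21)$npp,
      numeric(1)))
    add("o2", o2_range, vapply(o2_range, function(ox)
      photosynthesis_rate(p, 250, temp, saturation, 400, o2 = ox)$npp,
      numeric(1)))
  }
  do.call(rbind, rows)
}
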