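# Text-based I/O: long-format CSV export of gridded fields, run manifests,
# and a minimal structured-text (TOML-subset) configuration reader.

#' Write vegetation and weathering fields as long-format CSV
#'
#' One row per cell with longitude, latitude and all per-cell fields
#' (NPP, GPP, cover, biomass, runoff, weathering limits, realized
#' weathering and the limiting factor).
#'
#' @param veg a `veg_fields`.
#' @param wres an optional `weathering_result` on the same grid.
#' @param path output file.
#' @return the data.frame, invisibly.
#' @export
write_fields_csv <- function(veg, wres = NULL, path) {
  grid <- veg$grid
  df <- expand.grid(lon = grid$lon_centers, lat = grid$lat_centers)
  take <- function(m) as.vector(m)
  df$available <- take(veg$available)
  df$vegetated <- take(veg$vegetated)
  df$potential_npp <- take(veg$potential_npp)
  df$gpp <- take(veg$gpp)
  df$cover <- take(veg$cover)
  df$biomass <- take(veg$biomass)
  df$runoff <- take(veg$runoff)
  if (!is.null(wres)) {
    df$w_npp <- take(wres$w_npp)
    df$w_erosion <- take(wres$w_erosion)
    df$w_runoff <- take(wres$w_runoff)
    df$w_realized <- take(wres$w_realized)
    df$limiting_factor <- take(wres$limiting_factor)
    df$realized_npp <- take(wres$realized_npp)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Short fingerprint of a configuration object
#'
#' Deterministic hex digest of the deparsed object; recorded in run
#' manifests so outputs can be matched to the configuration that
#' produced them.
#'
#' @param x any R object.
#' @return an 8-character hex string.
#' @export
config_fingerprint <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  h <- 5381
  for (v in utf8ToInt(txt)) h <- (h * 33 + v) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Write a run manifest
#'
#' Plain-text `key = value` record of the experiment name, seed,
#' configuration fingerprint and all option values.
#'
#' @param path output file.
#' @param manifest list with `experiment`, `seed`, `fingerprint`,
#'   `options`.
#' @export
write_manifest <- function(path, manifest) {
  lines <- c(
    sprintf("experiment = %s", manifest$experiment),
    sprintf("seed = %s", manifest$seed),
    sprintf("fingerprint = %s", manifest$fingerprint),
    sprintf("package_version = %s",
            as.character(utils::packageVersion("cryptoweather"))),
    "",
    "[options]"
  )
  for (nm in names(manifest$options)) {
    lines <- c(lines, sprintf("%s = %s", nm,
                              paste(format(manifest$options[[nm]]),
                                    collapse = ", ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a structured configuration file (TOML subset)
#'
#' Supports `[section]` headers, `key = value` pairs with numbers,
#' booleans (`true`/`false`), quoted strings and flat numeric arrays
#' (`[1, 2, 3]`); `#` comments are stripped.
#'
#' @param path file path.
#' @return nested named list (one element per section).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  parse_value <- function(v) {
    v <- trimws(v)
    if (grepl("^\\[.*\\]$", v)) {
      parts <- strsplit(gsub("^\\[|\\]$", "", v), ",")[[1]]
      return(vapply(parts, function(p) as.numeric(trimws(p)), numeric(1),
                    USE.NAMES = FALSE))
    }
    if (v %in% c("true", "false")) return(v == "true")
    if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- out[[section]] %||% list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- parse_value(paste(kv[-1], collapse = "="))
      if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
    }
  }
  out
}

#' Default pipeline configuration
#'
#' The configuration mirrored by `inst/extdata/default_config.toml`:
#' section `climate` (grid, land fraction, CO2-temperature sensitivity,
#' seed), `vegetation` (species number, run length, disturbance interval,
#' universal physiological constants, atmospheric composition) and
#' `weathering` (stoichiometry, rock and soil chemistry, erosion
#' constant).
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    climate = list(n_lon = 48, n_lat = 24, land_fraction = 0.25,
                   temp_sensitivity_per_doubling = 3, seed = 1),
    vegetation = list(n_species = 30, n_years = 50, tau_d_years = 100,
                      phi_rr = 15, eta_ccm = 8, o2_fraction = 0.14,
                      co2_pal = 8),
    weathering = list(cp_mass_ratio = 350, recycling_ratio = 5,
                      p_conc = 1432, soil_pco2_ppm = 10000, k_e = 6e-8,
                      lithology = "mean")
  )
}
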