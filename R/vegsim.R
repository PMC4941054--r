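# Grid-level vegetation simulation: downscale the monthly climate of every
# land, non-glaciated cell to hourly forcing and run the per-cell model.

#' Run the vegetation model over all land cells
#'
#' For every land cell outside the prescribed glacier mask, the monthly
#' climate is disaggregated with the stochastic weather generator (each
#' cell drawing from its own seed sub-stream) and [run_cell()] is applied
#' to the full species pool. Cells where the dynamic snow balance
#' glaciates, or where no species survives, are flagged barren and carry
#' zero NPP.
#'
#' @param paleo a `paleogeography`.
#' @param climate a `monthly_climate` on the same grid.
#' @param species a `species_params` pool (shared by all cells).
#' @param seed master seed for the weather generator sub-streams.
#' @param cfg a [veg_config()].
#' @param progress print one line per cell (default FALSE).
#' @return object of class `veg_fields`: matrices `potential_npp`, `gpp`
#'   (g C m-2 yr-1), `cover`, `biomass` (g C m-2), `runoff` (mm yr-1),
#'   `n_survivors`, logical `vegetated` and `available` (land, not
#'   glaciated), `dominant` (index of the highest-weight species), the
#'   `grid`, and `cells` (per-cell results for diagnostics).
#' @export
run_grid <- function(paleo, climate, species, seed, cfg = veg_config(),
                     progress = FALSE) {
  grid <- paleo$grid
  if (!identical(dim(climate$temp)[1:2], c(grid$n_lon, grid$n_lat))) {
    stop("climate and paleogeography grids do not match", call. = FALSE)
  }
  zero <- matrix(0, grid$n_lon, grid$n_lat)
  out <- list(potential_npp = zero, gpp = zero, cover = zero,
              biomass = zero, runoff = zero, n_survivors = zero,
              vegetated = matrix(FALSE, grid$n_lon, grid$n_lat),
              available = paleo$land_mask & !paleo$glacier_mask,
              dominant = matrix(NA_integer_, grid$n_lon, grid$n_lat))
  cells <- list()

  idx <- which(out$available, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    forcing <- downscale_to_hourly(climate, derive_seed(seed, i, j), i = i, j = j)
    res <- run_cell(species, forcing, cfg)
    if (res$glaciated) out$available[i, j] <- FALSE
    if (!res$barren) {
      out$potential_npp[i, j] <- res$potential_npp
      out$gpp[i, j] <- res$gpp
      out$cover[i, j] <- res$cover
      out$biomass[i, j] <- res$biomass
      out$runoff[i, j] <- res$runoff
      out$n_survivors[i, j] <- res$n_survivors
      out$vegetated[i, j] <- TRUE
      out$dominant[i, j] <- which.max(res$species_weights)
    }
    cells[[paste(i, j, sep = "_")]] <- res
    if (progress) {
      cat(sprintf("cell (%d,%d): NPP %.1f g C m-2 yr-1, %d survivors\n",
                  i, j, res$potential_npp, res$n_survivors))
    }
  }
  structure(c(out, list(grid = grid, cells = cells, species = species)),
            class = "veg_fields")
}

#' @export
print.veg_fields <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    "<veg_fields> %d x %d: %d available cells, %d vegetated; mean NPP %.1f g C m-2 yr-1\n",
    g$n_lon, g$n_lat, sum(x$available), sum(x$vegetated),
    area_mean(x$potential_npp, g, mask = x$vegetated)))
  invisible(x)
}

#' Parameters of the highest-weight species of a vegetation run
#'
#' Identifies the species with the largest NPP-accumulated weight over all
#' vegetated cells (optionally restricted to a latitude band) and returns
#' its parameter row; used to extract run-adapted species for the
#' CO2/light/O2 response curves.
#'
#' @param veg a `veg_fields`.
#' @param lat_range optional latitude interval `c(lo, hi)` (deg).
#' @return a one-row `species_params`, or `NULL` if the run is barren.
#' @export
dominant_species <- function(veg, lat_range = NULL) {
  mask <- veg$vegetated
  if (!is.null(lat_range)) {
    lat <- grid_lat_matrix(veg$grid)
    mask <- mask & lat >= lat_range[1] & lat <= lat_range[2]
  }
  if (!any(mask)) return(NULL)
  # accumulate area-weighted weights per species over selected cells
  w_tot <- numeric(nrow(veg$species))
  for (key in names(veg$cells)) {
    ij <- as.integer(strsplit(key, "_")[[1]])
    if (!mask[ij[1], ij[2]]) next
    w_tot <- w_tot + veg$cells[[key]]$species_weights *
      veg$grid$cell_area[ij[1], ij[2]]
  }
  if (sum(w_tot) <= 0) return(NULL)
  veg$species[which.max(w_tot), , drop = FALSE]
}
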