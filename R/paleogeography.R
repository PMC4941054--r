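# Synthetic paleogeography: a southern-hemisphere-weighted supercontinent
# (Gondwana-like) plus low-latitude landmasses, with a smoothed random
# elevation field featuring coastal lowlands and interior highlands.

# Smooth a field with an iterated 3x3 box filter; longitude wraps around,
# latitude rows are clamped at the poles.
smooth_field <- function(x, passes = 2L) {
  n_lon <- nrow(x)
  n_lat <- ncol(x)
  for (p in seq_len(passes)) {
    xl <- x[c(n_lon, seq_len(n_lon - 1L)), , drop = FALSE]
    xr <- x[c(seq_len(n_lon - 1L) + 1L, 1L), , drop = FALSE]
    y <- (x + xl + xr) / 3
    yu <- y[, c(1L, seq_len(n_lat - 1L)), drop = FALSE]
    yd <- y[, c(seq_len(n_lat - 1L) + 1L, n_lat), drop = FALSE]
    x <- (y + yu + yd) / 3
  }
  x
}

# Grid distance (in cells, 4-neighbour BFS with longitude wrap) to the
# nearest FALSE cell of `mask`; used for interior-highland elevation.
distance_to_edge <- function(mask) {
  n_lon <- nrow(mask)
  n_lat <- ncol(mask)
  d <- matrix(Inf, n_lon, n_lat)
  d[!mask] <- 0
  repeat {
    dl <- d[c(n_lon, seq_len(n_lon - 1L)), , drop = FALSE]
    dr <- d[c(seq_len(n_lon - 1L) + 1L, 1L), , drop = FALSE]
    du <- cbind(Inf, d[, seq_len(n_lat - 1L), drop = FALSE])
    dd <- cbind(d[, seq_len(n_lat - 1L) + 1L, drop = FALSE], Inf)
    d_new <- pmin(d, dl + 1, dr + 1, du + 1, dd + 1)
    if (identical(d_new, d)) break
    d <- d_new
  }
  d
}

#' Generate a synthetic Ordovician-style paleogeography
#'
#' Land is placed by thresholding a latitudinally biased smoothed random
#' potential so that a configurable fraction of the globe is land; the bias
#' concentrates land in a south-polar supercontinent with secondary
#' low-latitude landmasses. Elevation on land combines a smoothed random
#' component with a distance-to-coast ramp (coastal lowlands, interior
#' highlands) and is zero over the ocean.
#'
#' @param grid a `grid_spec` from [make_grid()].
#' @param seed integer seed; identical seeds give identical fields.
#' @param scenario `"baseline"` (no prescribed ice) or `"hirnantian_ice"`
#'   (glacier mask on all land south of 30 deg S, the Hirnantian
#'   continental-ice configuration).
#' @param land_fraction fraction of the global surface that is land
#'   (default 0.25).
#' @param max_elevation approximate upper scale of interior elevation (m).
#' @return an object of class `paleogeography`: list with `land_mask`
#'   (logical matrix), `elevation` (m, 0 on ocean), `glacier_mask`,
#'   `scenario_tag`, and the `grid`.
#' @export
generate_paleogeography <- function(grid, seed, scenario = "baseline",
                                    land_fraction = 0.25,
                                    max_elevation = 1500) {
  if (!inherits(grid, "grid_spec")) stop("`grid` must be a grid_spec", call. = FALSE)
  if (!scenario %in% c("baseline", "hirnantian_ice")) {
    stop(sprintf("unknown scenario '%s'", scenario), call. = FALSE)
  }
  if (land_fraction <= 0 || land_fraction >= 1) {
    stop("`land_fraction` must be in (0, 1)", call. = FALSE)
  }
  lat <- grid_lat_matrix(grid)
  withr::with_seed(derive_seed(seed, 101L), {
    noise <- smooth_field(matrix(stats::rnorm(grid$n_lon * grid$n_lat),
                                 grid$n_lon, grid$n_lat), passes = 3L)
    # Latitudinal bias: strong south-polar supercontinent plus a weaker
    # low-latitude belt; noise breaks the zonal symmetry into landmasses.
    potential <- 1.6 * exp(-((lat + 60) / 28)^2) +
      0.7 * exp(-(lat / 25)^2) +
      1.4 * noise
    # Threshold at the area-weighted quantile that yields `land_fraction`.
    ord <- order(potential, decreasing = TRUE)
    cum <- cumsum(grid$cell_area[ord]) / sum(grid$cell_area)
    thr <- potential[ord][which(cum >= land_fraction)[1L]]
    land <- potential >= thr

    elev_noise <- smooth_field(matrix(stats::runif(grid$n_lon * grid$n_lat),
                                      grid$n_lon, grid$n_lat), passes = 2L)
  })
  dist <- distance_to_edge(land)
  dist_norm <- ifelse(is.finite(dist), dist / max(1, max(dist[is.finite(dist)])), 1)
  elevation <- land * (40 + max_elevation * dist_norm * (0.4 + 0.9 * elev_noise))
  elevation[!land] <- 0

  glacier <- matrix(FALSE, grid$n_lon, grid$n_lat)
  if (scenario == "hirnantian_ice") glacier <- land & (lat < -30)

  structure(
    list(land_mask = land, elevation = elevation, glacier_mask = glacier,
         scenario_tag = scenario, grid = grid),
    class = "paleogeography"
  )
}

#' @export
print.paleogeography <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    "<paleogeography> scenario '%s': land fraction %.2f, mean land elevation %.0f m, %d glaciated cells\n",
    x$scenario_tag,
    area_sum(x$land_mask + 0, g) / sum(g$cell_area),
    area_mean(x$elevation, g, mask = x$land_mask),
    sum(x$glacier_mask)))
  invisible(x)
}
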