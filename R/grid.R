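#' Regular latitude-longitude grid with cosine-weighted cell areas
#'
#' Builds a global grid of `n_lon` x `n_lat` cells on equally spaced
#' longitude/latitude edges. Cell areas are computed exactly from the
#' spherical zone formula, `A = R^2 * dlambda * (sin(phi2) - sin(phi1))`,
#' so that they sum to the surface area of the sphere.
#'
#' Fields on the grid are stored as matrices with dimensions
#' `c(n_lon, n_lat)`; monthly fields as arrays `c(n_lon, n_lat, 12)`.
#'
#' @param n_lon,n_lat number of longitude and latitude cells (each >= 4).
#' @return an object of class `grid_spec`: list with `n_lon`, `n_lat`,
#'   `lon_centers`, `lat_centers` (degrees), and `cell_area`
#'   (matrix, m^2, constant along longitude).
#' @examples
#' g <- make_grid(8, 8)
#' sum(g$cell_area) / (4 * pi * 6.371e6^2)  # ~1
#' @export
make_grid <- function(n_lon, n_lat) {
  if (!is.numeric(n_lon) || !is.numeric(n_lat) ||
      n_lon < 4 || n_lat < 4 ||
      n_lon != round(n_lon) || n_lat != round(n_lat)) {
    stop("`n_lon` and `n_lat` must be integers >= 4", call. = FALSE)
  }
  n_lon <- as.integer(n_lon)
  n_lat <- as.integer(n_lat)
  lon_edges <- seq(-180, 180, length.out = n_lon + 1L)
  lat_edges <- seq(-90, 90, length.out = n_lat + 1L)
  lon_centers <- (lon_edges[-1L] + lon_edges[-(n_lon + 1L)]) / 2
  lat_centers <- (lat_edges[-1L] + lat_edges[-(n_lat + 1L)]) / 2
  R <- .const$earth_radius
  dlam <- 2 * pi / n_lon
  zone <- R^2 * dlam * diff(sin(lat_edges * pi / 180))  # area per cell per band
  cell_area <- matrix(rep(zone, each = n_lon), nrow = n_lon, ncol = n_lat)
  structure(
    list(n_lon = n_lon, n_lat = n_lat,
         lon_centers = lon_centers, lat_centers = lat_centers,
         cell_area = cell_area),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, total area %.3e m^2\n",
              x$n_lon, x$n_lat, sum(x$cell_area)))
  invisible(x)
}

# Matrix of latitude (deg) per cell, same dims as fields on the grid.
grid_lat_matrix <- function(grid) {
  matrix(rep(grid$lat_centers, each = grid$n_lon),
         nrow = grid$n_lon, ncol = grid$n_lat)
}

#' Area-weighted global sum of a field over a mask
#'
#' @param field matrix `c(n_lon, n_lat)` of per-area quantities.
#' @param grid a `grid_spec`.
#' @param mask logical matrix selecting cells (default: all).
#' @return scalar: `sum(field * cell_area)` over the mask.
#' @export
area_sum <- function(field, grid, mask = NULL) {
  stopifnot(all(dim(field) == dim(grid$cell_area)))
  w <- grid$cell_area
  if (!is.null(mask)) w <- w * mask
  sum(field * w, na.rm = TRUE)
}

#' Area-weighted mean of a field over a mask
#' @inheritParams area_sum
#' @return scalar area-weighted mean.
#' @export
area_mean <- function(field, grid, mask = NULL) {
  w <- grid$cell_area
  if (!is.null(mask)) w <- w * mask
  sum(field * w, na.rm = TRUE) / sum(w + 0 * field, na.rm = TRUE)
}

# Zonal (latitude-band) mean of a field over an optional mask.
zonal_mean <- function(field, grid, mask = NULL) {
  w <- grid$cell_area
  if (!is.null(mask)) w <- w * mask
  num <- colSums(field * w, na.rm = TRUE)
  den <- colSums(w + 0 * field, na.rm = TRUE)
  ifelse(den > 0, num / den, NA_real_)
}
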