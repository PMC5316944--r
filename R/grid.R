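#' Build the discrete spatial domain for the grid filter
#'
#' Lays a regular lon/lat grid over an extent, samples bathymetry onto the
#' cell centroids and flags zero-depth cells as land. The hidden state of the
#' geolocation HMM is the index of a sea cell of this grid.
#'
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)`, degrees. The
#'   resolution must divide both spans.
#' @param resolution cell size, degrees.
#' @param bathymetry_field an `env_fields` object (or any object with a
#'   `bathy_at(field, lon, lat)` method) covering the extent.
#' @return a `grid_spec`: list with centroid vectors `lon`, `lat`,
#'   `resolution`, `extent`, `bathy` matrix `[lon, lat]` and logical `sea`
#'   mask.
#' @export
build_grid <- function(extent, resolution, bathymetry_field) {
  stopifnot(length(extent) == 4, resolution > 0)
  nx <- (extent[2] - extent[1]) / resolution
  ny <- (extent[4] - extent[3]) / resolution
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8)
    stop("resolution must divide the extent in both axes")
  lon <- extent[1] + (seq_len(round(nx)) - 0.5) * resolution
  lat <- extent[3] + (seq_len(round(ny)) - 0.5) * resolution
  bathy <- matrix(bathy_at(bathymetry_field,
                           rep(lon, times = length(lat)),
                           rep(lat, each = length(lon))),
                  length(lon), length(lat))
  sea <- bathy > 0
  if (!any(sea)) stop("grid has no sea cells")
  structure(list(lon = lon, lat = lat, resolution = resolution,
                 extent = extent, bathy = bathy, sea = sea),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", length(x$lon), "x", length(x$lat), " cells at ",
      x$resolution, " deg; ", sum(x$sea), " sea cells\n", sep = "")
  invisible(x)
}

# index of the cell containing a point (error if outside)
grid_cell <- function(grid, lon, lat) {
  i <- floor((lon - grid$extent[1]) / grid$resolution) + 1L
  j <- floor((lat - grid$extent[3]) / grid$resolution) + 1L
  if (any(i < 1 | i > length(grid$lon) | j < 1 | j > length(grid$lat)))
    stop("point outside grid extent")
  cbind(i, j)
}

# environment SST sampled at the grid centroids for one date
env_sst_on_grid <- function(env, grid, date) {
  matrix(sst_at(env,
                rep(grid$lon, times = length(grid$lat)),
                rep(grid$lat, each = length(grid$lon)),
                date),
         length(grid$lon), length(grid$lat))
}
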