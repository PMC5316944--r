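#' Aggregate daily posteriors into a utilisation distribution
#'
#' Normalises and sums (i.e. averages) the daily posterior surfaces over a
#' period, giving the probability of the animal's presence per grid cell for
#' its time at liberty. The default period is "post-summer": all days from
#' the first 1 October in the series onwards.
#'
#' @param fit an `hmm_fit`, or a list of posterior matrices with a `dates`
#'   attribute of equal length.
#' @param period_start first date to include; `NULL` (default) means the
#'   first 1 October on or after the series start; `FALSE` means the whole
#'   series.
#' @return a `ud` object: probability matrix with attributes `grid` and
#'   `period` (sums to 1).
#' @export
sum_uds <- function(fit, period_start = NULL) {
  if (inherits(fit, "hmm_fit")) {
    posts <- fit$posteriors; dates <- fit$dates; grid <- fit$grid
  } else {
    posts <- fit; dates <- attr(fit, "dates"); grid <- attr(fit, "grid")
  }
  if (isFALSE(period_start)) {
    keep <- rep(TRUE, length(dates))
  } else {
    if (is.null(period_start)) {
      y <- as.integer(format(min(dates), "%Y"))
      oct1 <- as.Date(paste0(y, "-10-01"))
      if (oct1 < min(dates)) oct1 <- as.Date(paste0(y + 1, "-10-01"))
      period_start <- oct1
    }
    keep <- dates >= as.Date(period_start)
  }
  if (!any(keep)) stop("no posteriors fall in the requested period")
  ud <- Reduce(`+`, posts[keep]) / sum(keep)
  ud <- ud / sum(ud)
  structure(ud, grid = grid, period = range(dates[keep]), class = "ud")
}

#' Percentage volume contour of a utilisation distribution
#'
#' The smallest set of cells, taken in descending probability order, whose
#' cumulative mass reaches `q_percent`/100 — the standard home-range
#' "density kernel" contour. Ties in cell probability are broken by stable
#' cell order, so only as many tied cells as needed are included.
#'
#' @param ud a probability matrix/vector (a `ud` object or any non-negative
#'   field summing to 1).
#' @param q_percent contour level in (0, 100].
#' @return logical mask of the same shape as `ud`; attribute `mass` holds the
#'   mass actually enclosed.
#' @export
pvc <- function(ud, q_percent) {
  stopifnot(q_percent > 0, q_percent <= 100)
  p <- as.numeric(ud)
  ord <- order(p, decreasing = TRUE)
  cs <- cumsum(p[ord])
  k <- which(cs >= q_percent / 100 - 1e-12)[1]
  if (is.na(k)) k <- length(ord)
  mask <- rep(FALSE, length(p))
  mask[ord[seq_len(k)]] <- TRUE
  mask <- mask & p > 0
  dim(mask) <- dim(ud)
  attr(mask, "mass") <- sum(p[mask])
  mask
}

## ---- azimuthal equidistant projection (for metric hex grids) ----

# forward: lon/lat (deg) -> x/y (km) about an origin
aeqd_forward <- function(lon, lat, origin) {
  R <- 6371
  lam <- lon * pi / 180; phi <- lat * pi / 180
  lam0 <- origin[1] * pi / 180; phi0 <- origin[2] * pi / 180
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(pmax(cosc, -1), 1)
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- R * k * cos(phi) * sin(lam - lam0)
  y <- R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  cbind(x = x, y = y)
}

# inverse: x/y (km) -> lon/lat (deg)
aeqd_inverse <- function(x, y, origin) {
  R <- 6371
  lam0 <- origin[1] * pi / 180; phi0 <- origin[2] * pi / 180
  c_ang <- sqrt(x^2 + y^2) / R
  phi <- ifelse(c_ang < 1e-12, phi0,
                asin(cos(c_ang) * sin(phi0) + y * sin(c_ang) * cos(phi0) / (R * c_ang)))
  lam <- lam0 + ifelse(c_ang < 1e-12, 0,
                       atan2(x * sin(c_ang),
                             R * c_ang * cos(phi0) * cos(c_ang) - y * sin(phi0) * sin(c_ang)))
  cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Build a hexagonal sampling grid
#'
#' Flat-topped regular hexagons tiling the extent, laid out in a local
#' azimuthal-equidistant projection about the extent centre so that the
#' apothem (centroid-to-edge distance) is metric. With the default 50-km
#' apothem each cell covers 2 * sqrt(3) * 50^2 = 8,660 km^2.
#'
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)`, degrees.
#' @param apothem_km centroid-to-edge distance, km.
#' @return a `hex_grid`: tibble of cell centres (`cell_id`, `x_km`, `y_km`,
#'   `lon`, `lat`) with attributes `origin`, `apothem_km`, `side_km`,
#'   `cell_area_km2`.
#' @export
build_hex_grid <- function(extent, apothem_km = 50) {
  stopifnot(apothem_km > 0)
  origin <- c(mean(extent[1:2]), mean(extent[3:4]))
  corners <- aeqd_forward(extent[c(1, 2, 1, 2)], extent[c(3, 3, 4, 4)], origin)
  pad <- 2 * apothem_km
  xr <- range(corners[, 1]) + c(-pad, pad)
  yr <- range(corners[, 2]) + c(-pad, pad)
  s <- 2 * apothem_km / sqrt(3)  # hexagon side = circumradius (flat-topped)

  cols <- seq(floor(xr[1] / (1.5 * s)), ceiling(xr[2] / (1.5 * s)))
  rows <- seq(floor(yr[1] / (2 * apothem_km)) - 1, ceiling(yr[2] / (2 * apothem_km)))
  cen <- expand.grid(col = cols, row = rows)
  cen$x <- 1.5 * s * cen$col
  cen$y <- 2 * apothem_km * cen$row + apothem_km * (cen$col %% 2)
  keep <- cen$x >= xr[1] & cen$x <= xr[2] & cen$y >= yr[1] & cen$y <= yr[2]
  cen <- cen[keep, , drop = FALSE]
  ll <- aeqd_inverse(cen$x, cen$y, origin)
  g <- tibble::tibble(cell_id = paste0("h", cen$col, "_", cen$row),
                      col = cen$col, row = cen$row,
                      x_km = cen$x, y_km = cen$y,
                      lon = ll[, 1], lat = ll[, 2])
  structure(g, origin = origin, apothem_km = apothem_km, side_km = s,
            cell_area_km2 = 2 * sqrt(3) * apothem_km^2,
            class = c("hex_grid", class(g)))
}

#' Assign points to hexagonal cells
#'
#' Exact point-in-hexagon containment via axial-coordinate rounding in the
#' grid's projected plane.
#'
#' @param lon,lat point coordinates, degrees.
#' @param hexgrid a [build_hex_grid()] result.
#' @return character vector of `cell_id`s (`NA` for points off the grid).
#' @export
hex_assign <- function(lon, lat, hexgrid) {
  origin <- attr(hexgrid, "origin"); s <- attr(hexgrid, "side_km")
  xy <- aeqd_forward(lon, lat, origin)
  # axial coords for flat-topped hexes, then cube rounding
  q <- (2 / 3) * xy[, 1] / s
  r <- (-xy[, 1] / 3 + sqrt(3) / 3 * xy[, 2]) / s
  rq <- round(q); rr <- round(r); rs <- round(-q - r)
  dq <- abs(rq - q); dr <- abs(rr - r); ds <- abs(rs - (-q - r))
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  rq[fix_q] <- -rr[fix_q] - rs[fix_q]
  rr[fix_r] <- -rq[fix_r] - rs[fix_r]
  col <- rq
  row <- rr + (col - (col %% 2)) / 2   # axial -> offset (odd columns shifted up)
  ids <- paste0("h", col, "_", row)
  ids[!ids %in% hexgrid$cell_id] <- NA_character_
  ids
}

#' Mean space-use density on a hexagonal grid
#'
#' Per animal, the proportion of its tracking days assigned to each hex cell
#' (point locations by containment; posterior rasters by apportioning each
#' raster cell's daily mass to the hex containing the raster-cell centroid),
#' followed by the unweighted mean across animals. Point and raster inputs
#' cannot be mixed in one call — run the two tag technologies separately.
#'
#' @param per_animal a list, one element per animal: either a tibble with
#'   `lon`, `lat` (daily point locations) or an `hmm_fit` (daily posterior
#'   rasters).
#' @param hexgrid a [build_hex_grid()] result.
#' @return tibble `cell_id`, `lon`, `lat`, `mean_density`, sorted by density.
#' @export
hex_density <- function(per_animal, hexgrid) {
  is_fit <- vapply(per_animal, inherits, TRUE, what = "hmm_fit")
  if (any(is_fit) && !all(is_fit))
    stop("cannot mix point tracks and posterior rasters in one call")
  per_cell <- function(animal) {
    if (inherits(animal, "hmm_fit")) {
      grid <- animal$grid
      cen_id <- hex_assign(rep(grid$lon, times = length(grid$lat)),
                           rep(grid$lat, each = length(grid$lon)), hexgrid)
      total <- Reduce(`+`, animal$posteriors)
      w <- tapply(as.numeric(total), cen_id, sum) / length(animal$posteriors)
    } else {
      ids <- hex_assign(animal$lon, animal$lat, hexgrid)
      w <- table(ids) / length(ids)
    }
    w
  }
  acc <- list()
  for (a in per_animal) {
    w <- per_cell(a)
    for (id in names(w)) acc[[id]] <- (acc[[id]] %||% 0) + w[[id]]
  }
  n <- length(per_animal)
  ids <- names(acc)
  m <- match(ids, hexgrid$cell_id)
  out <- tibble::tibble(cell_id = ids,
                        lon = hexgrid$lon[m], lat = hexgrid$lat[m],
                        mean_density = unname(unlist(acc)) / n)
  out[order(-out$mean_density), ]
}

#' Zone occupancy percentages
#'
#' Percentage of all animal-days falling inside each named zone polygon.
#' Zones are tested in input order and a location is assigned to the first
#' zone containing it; locations outside every zone count as `"High Seas"`.
#'
#' @param daily_locations tibble with `lon`, `lat` (one row per animal-day).
#' @param zones named list of polygons, each a two-column matrix/data frame
#'   of `lon`, `lat` vertices; see [read_zones_geojson()].
#' @return tibble `zone`, `n_days`, `percent` (percentages sum to 100).
#' @export
zone_occupancy <- function(daily_locations, zones) {
  n <- nrow(daily_locations)
  stopifnot(n > 0)
  pts <- cbind(daily_locations$lon, daily_locations$lat)
  assigned <- rep("High Seas", n)
  free <- rep(TRUE, n)
  for (nm in names(zones)) {
    if (!any(free)) break
    bnd <- as.matrix(as.data.frame(zones[[nm]]))
    inside <- mgcv::in.out(bnd, pts[free, , drop = FALSE])
    assigned[free][inside] <- nm
    free[free][inside] <- FALSE
  }
  lev <- c(names(zones), "High Seas")
  tab <- table(factor(assigned, levels = lev))
  tibble::tibble(zone = names(tab), n_days = as.integer(tab),
                 percent = 100 * as.numeric(tab) / n)
}

#' Read zone polygons from GeoJSON
#'
#' Accepts a FeatureCollection of `Polygon` features; the outer ring of each
#' polygon becomes one named zone (name from `properties$name`, else
#' `zone<i>`).
#'
#' @param path GeoJSON file path.
#' @return named list of two-column lon/lat vertex matrices.
#' @export
read_zones_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  zones <- list()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    if (!identical(f$geometry$type, "Polygon")) next
    ring <- f$geometry$coordinates[[1]]
    m <- t(vapply(ring, function(p) c(p[[1]], p[[2]]), numeric(2)))
    colnames(m) <- c("lon", "lat")
    nm <- f$properties$name %||% paste0("zone", i)
    zones[[nm]] <- m
  }
  zones
}

#' Write zone polygons to GeoJSON
#'
#' @param zones named list of two-column lon/lat vertex matrices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(zones, path) {
  feats <- lapply(names(zones), function(nm) {
    m <- as.matrix(as.data.frame(zones[[nm]]))
    if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])  # close the ring
    list(type = "Feature", properties = list(name = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(m)),
                                                   function(i) as.list(unname(m[i, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
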