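#' Generate synthetic environment fields (SST and bathymetry)
#'
#' Builds a gridded daily sea-surface temperature field and a static
#' bathymetry field over a lon/lat extent. The SST field combines a monotone
#' north--south gradient, a seasonal cycle and a smooth spatial anomaly, so
#' that an SST observation carries genuine (mostly latitudinal) position
#' information. The bathymetry emulates an eastern-boundary continental
#' margin: a land strip along the eastern edge, a shallow (< 200 m) shelf
#' hugging the coastline, a steep slope, and abyssal (> 2,000 m) open ocean
#' to the west. Cells with zero depth are land.
#'
#' @param extent numeric vector `c(lon_min, lon_max, lat_min, lat_max)` in
#'   degrees; must span at least 20 degrees of latitude and have positive area.
#' @param n_days number of daily SST slices to generate.
#' @param seed integer seed; the same seed reproduces the fields bit-for-bit.
#' @param resolution grid spacing in degrees (default 0.5).
#' @param start_date first date of the SST series (default 1 August 2012,
#'   a typical mid-summer tag deployment).
#' @return An object of class `env_fields`: a list with `lon`, `lat` (cell
#'   centroid vectors), `dates`, `sst` (array `[lon, lat, day]`, degrees C),
#'   `bathy` (matrix `[lon, lat]`, metres, positive down, 0 on land),
#'   `extent` and `resolution`.
#' @export
make_environment <- function(extent, n_days = 365L, seed = 1L,
                             resolution = 0.5,
                             start_date = as.Date("2012-08-01")) {
  stopifnot(length(extent) == 4, is.finite(extent))
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("degenerate extent: bounding box must have positive area")
  if (extent[4] - extent[3] < 20)
    stop("extent must span at least 20 degrees of latitude")
  stopifnot(n_days >= 1, resolution > 0)

  set.seed(as.integer(seed))
  lon <- seq(extent[1] + resolution / 2, extent[2] - resolution / 2, by = resolution)
  lat <- seq(extent[3] + resolution / 2, extent[4] - resolution / 2, by = resolution)
  nlon <- length(lon); nlat <- length(lat)
  dates <- start_date + seq_len(n_days) - 1L

  # --- bathymetry: sinuous coastline on the eastern edge, land to its east
  coast_lon <- extent[2] - 1.5 + 0.8 * sin(2 * pi * (lat - extent[3]) / 18)
  dist_w <- outer(rep(1, nlon), coast_lon) - matrix(lon, nlon, nlat)  # deg east of each cell to coast
  # negative dist_w (cell east of coast) => land
  bathy <- matrix(0, nlon, nlat)
  shelf <- dist_w > 0 & dist_w <= 3
  slope <- dist_w > 3 & dist_w <= 6
  abyss <- dist_w > 6
  bathy[shelf] <- 15 + (180 - 15) * dist_w[shelf] / 3
  bathy[slope] <- 180 + (2800 - 180) * (dist_w[slope] - 3) / 3
  rough <- smooth_random_field(lon, lat, n_modes = 6, wavelength_deg = 8)
  bathy[abyss] <- 3200 + 500 * rough[abyss]
  bathy[abyss] <- pmax(bathy[abyss], 2100)  # abyssal plain stays deep
  bathy[bathy < 0] <- 0

  # --- SST: latitudinal gradient + seasonal cycle + static spatial anomaly
  anom <- 0.6 * smooth_random_field(lon, lat, n_modes = 8, wavelength_deg = 5)
  base <- 24 - 0.35 * (outer(rep(1, nlon), lat) - 30)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- 3 * cos(2 * pi * (doy - 227) / 365.25)  # peak mid-August
  sst <- array(NA_real_, c(nlon, nlat, n_days))
  for (d in seq_len(n_days)) sst[, , d] <- base + anom + seasonal[d]

  structure(
    list(lon = lon, lat = lat, dates = dates, sst = sst, bathy = bathy,
         extent = extent, resolution = resolution),
    class = "env_fields"
  )
}

# Smooth pseudo-random surface as a sum of random plane waves, scaled to
# roughly unit amplitude; deterministic given the RNG state.
smooth_random_field <- function(lon, lat, n_modes = 8, wavelength_deg = 5) {
  f <- matrix(0, length(lon), length(lat))
  for (k in seq_len(n_modes)) {
    th <- runif(1, 0, 2 * pi)
    wl <- wavelength_deg * runif(1, 0.7, 1.6)
    ph <- runif(1, 0, 2 * pi)
    f <- f + outer(lon, lat, function(x, y)
      sin(2 * pi * (cos(th) * x + sin(th) * y) / wl + ph))
  }
  f / sqrt(n_modes / 2)
}

#' @export
print.env_fields <- function(x, ...) {
  cat("<env_fields> ", length(x$lon), "x", length(x$lat), " cells at ",
      x$resolution, " deg, ", length(x$dates), " days (",
      format(x$dates[1]), " .. ", format(x$dates[length(x$dates)]), ")\n",
      sep = "")
  cat("  sea fraction: ", round(mean(x$bathy > 0), 3), "\n", sep = "")
  invisible(x)
}

# nearest-cell index lookup (clamped to the grid)
env_index <- function(env, lon, lat) {
  i <- pmin(pmax(round((lon - env$lon[1]) / env$resolution) + 1L, 1L), length(env$lon))
  j <- pmin(pmax(round((lat - env$lat[1]) / env$resolution) + 1L, 1L), length(env$lat))
  cbind(i, j)
}

#' Sample environment fields at points
#'
#' Nearest-cell lookup of bathymetry or dated SST at arbitrary lon/lat
#' points. `bathy_at()` is generic: besides `env_fields` objects it accepts
#' a plain `function(lon, lat)` returning depths, which is convenient for
#' idealised test domains (e.g. uniform-depth open ocean).
#'
#' @param env an `env_fields` object, or for `bathy_at()` a function of
#'   `(lon, lat)`.
#' @param lon,lat coordinate vectors, degrees.
#' @param date a `Date` (required for SST; recycled).
#' @return numeric vector of sampled values.
#' @export
bathy_at <- function(env, lon, lat) UseMethod("bathy_at")

#' @export
bathy_at.env_fields <- function(env, lon, lat) {
  ij <- env_index(env, lon, lat)
  env$bathy[ij]
}

#' @export
bathy_at.function <- function(env, lon, lat) {
  as.numeric(env(lon, lat))
}

#' @rdname bathy_at
#' @export
sst_at <- function(env, lon, lat, date) {
  d <- match(as.Date(date), env$dates)
  if (anyNA(d)) stop("date outside the environment's SST series")
  ij <- env_index(env, lon, lat)
  env$sst[cbind(ij, rep_len(d, nrow(ij)))]
}

#' Write / read environment fields as plain-text grids
#'
#' Serialises an `env_fields` object to a single human-readable text file
#' (header lines, then bathymetry, then one SST block per day, all as
#' whitespace-separated values in `[lon, lat]` layout).
#'
#' @param env an `env_fields` object.
#' @param path file path.
#' @return `write_env_grid` returns `path` invisibly; `read_env_grid` returns
#'   the reconstructed `env_fields` object.
#' @export
write_env_grid <- function(env, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# basktrack environment grid"),
    paste("extent", paste(env$extent, collapse = " ")),
    paste("resolution", env$resolution),
    paste("n_days", length(env$dates)),
    paste("start_date", format(env$dates[1])),
    paste("nlon", length(env$lon)),
    paste("nlat", length(env$lat)),
    "bathy"
  ), con)
  write.table(env$bathy, con, row.names = FALSE, col.names = FALSE)
  for (d in seq_along(env$dates)) {
    writeLines(paste("sst_day", d), con)
    write.table(round(env$sst[, , d], 4), con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_env_grid
#' @export
read_env_grid <- function(path) {
  ln <- readLines(path)
  get_field <- function(key) strsplit(ln[startsWith(ln, key)][1], " ")[[1]][-1]
  extent <- as.numeric(get_field("extent"))
  res <- as.numeric(get_field("resolution"))
  n_days <- as.integer(get_field("n_days"))
  start <- as.Date(get_field("start_date"))
  nlon <- as.integer(get_field("nlon")); nlat <- as.integer(get_field("nlat"))
  body <- ln[!grepl("^(#|extent|resolution|n_days|start_date|nlon|nlat|bathy|sst_day)", ln)]
  vals <- scan(text = body, quiet = TRUE)
  ncell <- nlon * nlat
  # text blocks are row-major (one lon row per line)
  bathy <- matrix(vals[seq_len(ncell)], nlon, nlat, byrow = TRUE)
  sst <- array(NA_real_, c(nlon, nlat, n_days))
  for (d in seq_len(n_days))
    sst[, , d] <- matrix(vals[d * ncell + seq_len(ncell)], nlon, nlat,
                         byrow = TRUE)
  lon <- seq(extent[1] + res / 2, extent[2] - res / 2, by = res)
  lat <- seq(extent[3] + res / 2, extent[4] - res / 2, by = res)
  structure(
    list(lon = lon, lat = lat, dates = start + seq_len(n_days) - 1L,
         sst = sst, bathy = bathy, extent = extent, resolution = res),
    class = "env_fields"
  )
}
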