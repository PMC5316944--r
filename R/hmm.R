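#' Grid-filter configuration
#'
#' Parameters of the geolocation hidden Markov model. Defaults are the
#' values used for basking-shark archival tags: horizontal diffusion
#' coefficient 1,000 km^2/day, light-fix standard deviations of 1 degree
#' longitude and 3.5 degrees latitude, and 0.5 degrees C for the mismatch
#' between tag-recorded and satellite SST. The movement kernel is the
#' advection--diffusion equation; with the default zero advection velocity it
#' reduces to pure isotropic diffusion.
#'
#' @param D diffusion coefficient, km^2/day.
#' @param sigma_lon,sigma_lat light-fix SD, degrees.
#' @param sigma_sst SST observation SD, degrees C.
#' @param u_kmd,v_kmd eastward / northward advection velocity, km/day.
#' @return a `filter_config` list.
#' @export
filter_config <- function(D = 1000, sigma_lon = 1.0, sigma_lat = 3.5,
                          sigma_sst = 0.5, u_kmd = 0, v_kmd = 0) {
  stopifnot(D >= 0, sigma_lon > 0, sigma_lat > 0, sigma_sst > 0)
  structure(list(D = D, sigma_lon = sigma_lon, sigma_lat = sigma_lat,
                 sigma_sst = sigma_sst, u_kmd = u_kmd, v_kmd = v_kmd),
            class = "filter_config")
}

check_normalised <- function(p, tol = 1e-6) {
  if (any(p < 0) || abs(sum(p) - 1) > tol)
    stop("probability field must be non-negative and sum to 1")
  invisible(p)
}

# Linear movement kernel: one application of the discretised
# advection-diffusion operator over dt_days, flux-form explicit finite
# differences with internal sub-stepping (stability bound D*dt/dx^2 <= 0.25
# per axis per sub-step), no-flux boundaries at coastlines and domain edges.
# Conserves total mass exactly and never moves mass onto land. Longitudinal
# cell width scales with cos(latitude) of the cell row.
apply_movement_kernel <- function(p, grid, config, dt_days) {
  if (config$D == 0 && config$u_kmd == 0 && config$v_kmd == 0) return(p)
  nx <- length(grid$lon); ny <- length(grid$lat)
  dy <- KM_PER_DEG * grid$resolution
  dx <- KM_PER_DEG * grid$resolution * cos(grid$lat * pi / 180)  # per lat column
  sea <- grid$sea

  dmin <- min(dx, dy)
  rate <- config$D / dmin^2 + (abs(config$u_kmd) + abs(config$v_kmd)) / dmin
  nsub <- max(1L, ceiling(dt_days * rate / 0.25))
  dt <- dt_days / nsub

  ax <- config$D * dt / dx^2          # length ny (per column)
  ay <- config$D * dt / dy^2
  cx <- config$u_kmd * dt / dx        # Courant numbers for upwind advection
  cy <- config$v_kmd * dt / dy

  open_x <- sea[-nx, , drop = FALSE] & sea[-1, , drop = FALSE]
  open_y <- sea[, -ny, drop = FALSE] & sea[, -1, drop = FALSE]
  axm <- matrix(ax, nx - 1, ny, byrow = TRUE)
  cxm <- matrix(cx, nx - 1, ny, byrow = TRUE)

  for (s in seq_len(nsub)) {
    if (config$D > 0) {
      fx <- axm * (p[-1, , drop = FALSE] - p[-nx, , drop = FALSE]) * open_x
      fy <- ay * (p[, -1, drop = FALSE] - p[, -ny, drop = FALSE]) * open_y
    } else { fx <- 0 * open_x; fy <- 0 * open_y }
    if (config$u_kmd != 0)  # donor-cell upwind, zero flux through coasts
      fx <- fx - (pmax(cxm, 0) * p[-nx, , drop = FALSE] +
                    pmin(cxm, 0) * p[-1, , drop = FALSE]) * open_x
    if (config$v_kmd != 0)
      fy <- fy - (pmax(cy, 0) * p[, -ny, drop = FALSE] +
                    pmin(cy, 0) * p[, -1, drop = FALSE]) * open_y
    p[-nx, ] <- p[-nx, , drop = FALSE] + fx
    p[-1, ]  <- p[-1, , drop = FALSE] - fx
    p[, -ny] <- p[, -ny, drop = FALSE] + fy
    p[, -1]  <- p[, -1, drop = FALSE] - fy
  }
  p
}

#' Prediction step of the grid filter
#'
#' Propagates a daily posterior forward in time by solving the
#' advection--diffusion equation for the two-dimensional probability of the
#' animal's presence, with an explicit finite-difference scheme. Reflecting
#' (no-flux) boundaries at coastlines and the domain edge conserve total
#' probability to machine precision.
#'
#' @param posterior normalised probability matrix `[lon, lat]` on `grid`.
#' @param grid a `grid_spec`.
#' @param config a [filter_config()].
#' @param dt_days time step, days (> 0).
#' @return the predicted probability field (still sums to 1).
#' @export
predict_step <- function(posterior, grid, config = filter_config(),
                         dt_days = 1) {
  stopifnot(dt_days > 0)
  check_normalised(posterior)
  apply_movement_kernel(posterior, grid, config, dt_days)
}

#' Observation likelihood fields
#'
#' `light_likelihood()` evaluates independent Gaussians in longitude
#' (default SD 1 degree) and latitude (default SD 3.5 degrees) centred on the
#' raw light-based fix at every cell centroid. `sst_likelihood()` evaluates a
#' Gaussian (default SD 0.5 degrees C) of the difference between the
#' tag-recorded SST and the environment SST field on the date.
#' `depth_mask()` is the bathymetric constraint: a cell is admissible only if
#' its seafloor is at least as deep as the tag's daily maximum depth. All
#' fields are unnormalised; a missing observation yields an uninformative
#' field.
#'
#' @param light_fix numeric `c(lon, lat)`, or `NULL`/`NA` for a missing fix.
#' @param grid a `grid_spec`.
#' @param config a [filter_config()].
#' @return a matrix `[lon, lat]` of likelihood values (binary for
#'   `depth_mask`; an all-zero depth mask carries attribute
#'   `contradictory = TRUE`).
#' @export
light_likelihood <- function(light_fix, grid, config = filter_config()) {
  if (is.null(light_fix) || anyNA(light_fix))
    return(matrix(1, length(grid$lon), length(grid$lat)))
  outer(dnorm(grid$lon, light_fix[1], config$sigma_lon),
        dnorm(grid$lat, light_fix[2], config$sigma_lat))
}

#' @rdname light_likelihood
#' @param sst_obs tag-recorded SST, degrees C (`NA` for missing).
#' @param env_sst matrix of environment SST on the grid for the date.
#' @export
sst_likelihood <- function(sst_obs, env_sst, config = filter_config()) {
  if (is.null(sst_obs) || is.na(sst_obs))
    return(matrix(1, nrow(env_sst), ncol(env_sst)))
  exp(-0.5 * ((sst_obs - env_sst) / config$sigma_sst)^2)
}

#' @rdname light_likelihood
#' @param max_depth_obs daily maximum depth, metres (`NA` for missing).
#' @export
depth_mask <- function(max_depth_obs, grid) {
  if (is.null(max_depth_obs) || is.na(max_depth_obs))
    return(grid$sea * 1)
  if (max_depth_obs < 0) stop("max depth observation must be >= 0")
  m <- (grid$bathy >= max_depth_obs & grid$sea) * 1
  if (sum(m) == 0) attr(m, "contradictory") <- TRUE
  m
}

#' Update step of the grid filter
#'
#' Bayes update: posterior proportional to prior times the product of the
#' likelihood fields, renormalised. If the product has zero total mass the
#' contradictory constraint is dropped and the update retried — depth mask
#' first, then SST — with a warning; if the fields disagree beyond repair the
#' update fails, naming the date.
#'
#' @param prior normalised prior field `[lon, lat]`.
#' @param likelihoods named list of likelihood matrices; names among
#'   `"light"`, `"sst"`, `"depth"` drive the drop order.
#' @param date optional date, used in messages.
#' @return the normalised posterior matrix.
#' @export
update_step <- function(prior, likelihoods = list(), date = NULL) {
  check_normalised(prior)
  combine <- function(keep) {
    post <- prior
    for (nm in keep) post <- post * likelihoods[[nm]]
    post
  }
  keep <- names(likelihoods) %||% character()
  if (length(likelihoods) && is.null(names(likelihoods)))
    keep <- names(likelihoods) <- paste0("lik", seq_along(likelihoods))
  post <- combine(keep)
  for (drop in intersect(c("depth", "sst"), keep)) {
    if (sum(post) > 0) break
    warning(sprintf("contradictory %s observation%s dropped%s", drop,
                    if (is.null(date)) "" else paste0(" on ", format(date)),
                    ""), call. = FALSE)
    keep <- setdiff(keep, drop)
    post <- combine(keep)
  }
  if (sum(post) == 0)
    stop(sprintf("all observations contradictory%s",
                 if (is.null(date)) "" else paste0(" on ", format(date))))
  post / sum(post)
}

#' Run the geolocation grid filter over a tag's observations
#'
#' The HMM alternates a prediction step (advection--diffusion of the
#' probability surface) with a Bayes update against the day's light fix, SST
#' and maximum-depth observations. Day 0 is a point mass at the known
#' deployment location. Days without observations are predict-only. If a
#' pop-off (tag detachment) location is known, a forward--backward smoothing
#' pass anchors the final day at the pop-off cell and propagates the
#' constraint backwards through the whole track.
#'
#' @param observations the `light` tibble of an `obs_series` (columns `date`,
#'   `light_lon`, `light_lat`, `sst_c`, `max_depth_m`), or `NULL` for a
#'   predict-only chain.
#' @param grid a `grid_spec`.
#' @param config a [filter_config()].
#' @param deployment list with `date`, `lon`, `lat`, and optionally `popoff`
#'   (itself a list with `date`, `lon`, `lat`).
#' @param env an `env_fields` supplying the SST field (may be `NULL` if the
#'   observations carry no SST, or to ignore SST).
#' @param end_date last day to filter to (defaults to the last observation
#'   date, or the pop-off date if later).
#' @return an `hmm_fit`: list with `dates`, `posteriors` (list of `[lon,lat]`
#'   matrices, one per day, each summing to 1 with zero mass on land),
#'   `grid`, `config` and logical `smoothed`.
#' @export
run_filter <- function(observations, grid, config = filter_config(),
                       deployment = NULL, env = NULL, end_date = NULL) {
  stopifnot(!is.null(deployment))
  popoff <- deployment$popoff
  start <- as.Date(deployment$date)
  end <- as.Date(end_date %||% max(c(
    if (!is.null(observations) && nrow(observations)) max(observations$date),
    if (!is.null(popoff)) as.Date(popoff$date),
    start)))
  if (!is.null(observations) && nrow(observations) &&
      min(observations$date) < start)
    stop("observation dates precede the deployment date")
  dates <- seq(start, end, by = "day")
  Tn <- length(dates)

  point_mass <- function(lon, lat) {
    p <- matrix(0, length(grid$lon), length(grid$lat))
    p[grid_cell(grid, lon, lat)] <- 1
    p
  }
  p0 <- point_mass(deployment$lon, deployment$lat)  # errors if outside grid

  obs_row <- function(d) {
    if (is.null(observations) || !nrow(observations)) return(NULL)
    r <- observations[observations$date == d, , drop = FALSE]
    if (nrow(r)) r[1, ] else NULL
  }
  day_likelihoods <- function(d) {
    r <- obs_row(d)
    lik <- list()
    if (!is.null(r)) {
      if (!is.na(r$light_lon) && !is.na(r$light_lat))
        lik$light <- light_likelihood(c(r$light_lon, r$light_lat), grid, config)
      if (!is.null(r$sst_c) && !is.na(r$sst_c) && !is.null(env))
        lik$sst <- sst_likelihood(r$sst_c, env_sst_on_grid(env, grid, d), config)
      if (!is.null(r$max_depth_m) && !is.na(r$max_depth_m))
        lik$depth <- depth_mask(r$max_depth_m, grid)
    }
    if (!is.null(popoff) && d == as.Date(popoff$date))
      lik$popoff <- point_mass(popoff$lon, popoff$lat)
    lik
  }

  # forward pass
  posts <- vector("list", Tn)
  liks <- vector("list", Tn)
  posts[[1]] <- p0
  liks[[1]] <- list()
  for (t in seq_len(Tn)[-1]) {
    prior <- apply_movement_kernel(posts[[t - 1]], grid, config, 1)
    liks[[t]] <- day_likelihoods(dates[t])
    posts[[t]] <- if (length(liks[[t]]))
      update_step(prior, liks[[t]], date = dates[t]) else prior
  }

  smoothed <- !is.null(popoff)
  if (smoothed && Tn > 1) {
    # backward (beta) recursion: the movement kernel is self-adjoint under
    # the flux-form discretisation, so the same operator propagates beta
    beta <- matrix(1, length(grid$lon), length(grid$lat))
    for (t in rev(seq_len(Tn - 1))) {
      lk <- beta
      for (nm in names(liks[[t + 1]])) lk <- lk * liks[[t + 1]][[nm]]
      beta <- apply_movement_kernel(lk / sum(lk), grid, config, 1)
      g <- posts[[t]] * beta
      posts[[t]] <- g / sum(g)
    }
  }

  structure(list(dates = dates, posteriors = posts, grid = grid,
                 config = config, smoothed = smoothed),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("<hmm_fit> ", length(x$dates), " daily posteriors (",
      format(x$dates[1]), " .. ", format(x$dates[length(x$dates)]), "), ",
      if (x$smoothed) "smoothed" else "filtered", "\n", sep = "")
  invisible(x)
}

#' Best daily location from a posterior surface
#'
#' The single best position estimate for a day is the geographic mean of the
#' grid cell centroids weighted by their posterior probability (a weighted
#' arithmetic mean in degrees, adequate for sub-basin domains with unimodal
#' posteriors).
#'
#' @param posterior normalised probability matrix `[lon, lat]`.
#' @param grid the `grid_spec` the posterior lives on.
#' @return numeric `c(lon, lat)`.
#' @export
best_daily_location <- function(posterior, grid) {
  check_normalised(posterior)
  c(lon = sum(posterior * grid$lon),
    lat = sum(t(posterior) * grid$lat))
}

#' Best daily locations of a fitted track
#'
#' @param fit an `hmm_fit` from [run_filter()].
#' @param animal_id identifier copied into the output.
#' @return tibble with `animal_id`, `date`, `lon`, `lat`, `source`.
#' @export
best_track <- function(fit, animal_id = NA_character_) {
  xy <- t(vapply(fit$posteriors, best_daily_location, numeric(2),
                 grid = fit$grid))
  tibble::tibble(animal_id = animal_id, date = fit$dates,
                 lon = xy[, 1], lat = xy[, 2], source = "light-hmm")
}
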