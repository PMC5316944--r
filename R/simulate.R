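#' Simulation configuration
#'
#' Collects the observation-noise and surfacing parameters used by
#' [simulate_observations()]. Defaults follow the noise levels assumed by the
#' geolocation filter: light-fix standard deviations of 1 degree longitude and
#' 3.5 degrees latitude, and 0.5 degrees C between tag-recorded and satellite
#' SST. Surfacing probabilities reflect that basking sharks surface far less
#' in winter, which is what makes Argos coverage seasonal.
#'
#' @param seed integer seed.
#' @param n_animals number of animals in a cohort simulation.
#' @param strategy_mix named proportions over strategies `a`, `b`, `c`
#'   (must sum to 1).
#' @param sigma_lon_deg,sigma_lat_deg light-fix noise SD, degrees.
#' @param sigma_sst_c SST observation noise SD, degrees C.
#' @param light_miss_prob probability a day has no usable light fix.
#' @param surface_prob_summer,surface_prob_winter daily probability of at
#'   least one Argos surfacing fix (winter = October--March).
#' @param depth_cap_m physiological maximum for daily max depth, metres.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_animals = 12L,
                       strategy_mix = c(a = 0.5, b = 0.4, c = 0.1),
                       sigma_lon_deg = 1.0, sigma_lat_deg = 3.5,
                       sigma_sst_c = 0.5, light_miss_prob = 0.1,
                       surface_prob_summer = 0.7, surface_prob_winter = 0.15,
                       depth_cap_m = 1250) {
  stopifnot(sigma_lon_deg >= 0, sigma_lat_deg >= 0, sigma_sst_c >= 0,
            light_miss_prob >= 0, light_miss_prob < 1)
  if (abs(sum(strategy_mix) - 1) > 1e-8) stop("strategy_mix must sum to 1")
  structure(as.list(environment()), class = "sim_config")
}

# Winter half-year (southward phase): October through March.
is_winter <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  m >= 10 | m <= 3
}

#' Simulate a true migratory track
#'
#' Generates a daily-resolution ground-truth track as a biased correlated
#' random walk. From 1 October the drift points towards a strategy-specific
#' wintering latitude south of the deployment (strategy `a`: about 3 degrees
#' south, `b`: about 10 degrees, `c`: about 20 degrees); from 1 March it
#' reverses towards the deployment location, producing a seasonal return
#' migration. The walk never steps onto land (bathymetry 0) or out of the
#' environment extent, and daily displacement is capped at 150 km.
#'
#' @param deployment list with `animal_id`, `date` (a `Date`), `lon`, `lat`.
#' @param strategy one of `"a"`, `"b"`, `"c"`.
#' @param env an `env_fields` object (provides the land mask).
#' @param seed integer seed.
#' @param n_days track length in days (default 365).
#' @param step_sd_km per-axis SD of the daily velocity innovation, km/day.
#' @param max_drift_kmd maximum magnitude of the directed drift, km/day.
#' @param persistence autocorrelation of the daily velocity (0 = uncorrelated).
#' @return a `true_track` tibble with columns `animal_id`, `date`, `lon`,
#'   `lat` and attributes `strategy` and `deployment`.
#' @export
simulate_track <- function(deployment, strategy, env, seed,
                           n_days = 365L, step_sd_km = 8,
                           max_drift_kmd = 30, persistence = 0.6) {
  stopifnot(strategy %in% c("a", "b", "c"))
  if (bathy_at(env, deployment$lon, deployment$lat) <= 0)
    stop("deployment location is on land")
  set.seed(as.integer(seed))

  south_shift <- c(a = 3, b = 10, c = 20)[[strategy]]
  dates <- as.Date(deployment$date) + seq_len(n_days) - 1L
  lon <- numeric(n_days); lat <- numeric(n_days)
  lon[1] <- deployment$lon; lat[1] <- deployment$lat
  v <- c(0, 0)  # km/day (east, north)
  margin <- 0.5

  for (t in 2:n_days) {
    target <- if (is_winter(dates[t]))
      c(deployment$lon, deployment$lat - south_shift)
    else
      c(deployment$lon, deployment$lat)
    dx <- (target[1] - lon[t - 1]) * KM_PER_DEG * cos(lat[t - 1] * pi / 180)
    dy <- (target[2] - lat[t - 1]) * KM_PER_DEG
    dist <- sqrt(dx^2 + dy^2)
    drift <- if (dist > 0) c(dx, dy) / dist * min(max_drift_kmd, dist / 3) else c(0, 0)
    v <- persistence * v + (1 - persistence) * drift + rnorm(2, 0, step_sd_km)
    spd <- sqrt(sum(v^2))
    if (spd > 150) v <- v * 150 / spd  # plausible daily swim distance cap

    step_deg <- function(vv, la) c(vv[1] / (KM_PER_DEG * cos(la * pi / 180)),
                                   vv[2] / KM_PER_DEG)
    ok <- function(p) {
      p[1] > env$extent[1] + margin && p[1] < env$extent[2] - margin &&
        p[2] > env$extent[3] + margin && p[2] < env$extent[4] - margin &&
        bathy_at(env, p[1], p[2]) > 0
    }
    cand <- c(lon[t - 1], lat[t - 1]) + step_deg(v, lat[t - 1])
    if (!ok(cand)) {  # reflect off coast / domain edge
      for (flip in list(c(-1, 1), c(1, -1), c(-1, -1), c(0, 0))) {
        v2 <- v * flip
        cand <- c(lon[t - 1], lat[t - 1]) + step_deg(v2, lat[t - 1])
        if (ok(cand)) { v <- v2; break }
      }
      if (!ok(cand)) { cand <- c(lon[t - 1], lat[t - 1]); v <- c(0, 0) }
    }
    lon[t] <- cand[1]; lat[t] <- cand[2]
  }

  structure(
    tibble::tibble(animal_id = deployment$animal_id, date = dates,
                   lon = lon, lat = lat),
    strategy = strategy, deployment = deployment, class = c("true_track", class(tibble::tibble()))
  )
}

#' Simulate tag observations from a true track
#'
#' Produces the two observation streams an instrumented animal yields:
#' (i) an archival-tag daily series — light-based position fix (true position
#' plus independent zero-mean Gaussian noise in lon and lat, missing with a
#' configurable probability), tag-recorded SST (environment SST at the true
#' position plus Gaussian noise) and daily maximum depth (a right-skewed draw
#' concentrated in the 50--200 m band, never exceeding the local bathymetry
#' nor a 1,250 m physiological cap); and (ii) intermittent Argos surface
#' fixes with location classes 3, 2, 1, 0, A, B of increasing positional
#' error (0.25, 0.5, 1, 2, 5, 10 km), emitted with a seasonal daily
#' surfacing probability.
#'
#' @param track a `true_track` from [simulate_track()].
#' @param env the `env_fields` the track was simulated on.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return an `obs_series` list with tibbles `light` (`date`, `light_lon`,
#'   `light_lat`, `sst_c`, `max_depth_m`) and `argos` (`timestamp`, `lon`,
#'   `lat`, `loc_class`), plus the `animal_id`.
#' @export
simulate_observations <- function(track, env, config = sim_config(), seed = 1L) {
  if (min(track$date) < min(env$dates) || max(track$date) > max(env$dates))
    stop("track dates fall outside the environment's SST series")
  set.seed(as.integer(seed))
  n <- nrow(track)

  miss <- runif(n) < config$light_miss_prob
  light_lon <- track$lon + rnorm(n, 0, config$sigma_lon_deg)
  light_lat <- track$lat + rnorm(n, 0, config$sigma_lat_deg)
  light_lon[miss] <- NA_real_; light_lat[miss] <- NA_real_

  sst <- sst_at(env, track$lon, track$lat, track$date) +
    rnorm(n, 0, config$sigma_sst_c)

  cap <- pmin(bathy_at(env, track$lon, track$lat), config$depth_cap_m)
  depth <- pmin(cap, rlnorm(n, meanlog = log(110), sdlog = 0.8))

  light <- tibble::tibble(date = track$date, light_lon = light_lon,
                          light_lat = light_lat, sst_c = sst,
                          max_depth_m = depth)

  # Argos stream: class-dependent noise, fewer surfacings in winter
  p_surf <- ifelse(is_winter(track$date),
                   config$surface_prob_winter, config$surface_prob_summer)
  surfaced <- runif(n) < p_surf
  classes <- c("3", "2", "1", "0", "A", "B")
  class_p <- c(0.08, 0.12, 0.15, 0.15, 0.25, 0.25)
  err_km <- c(`3` = 0.25, `2` = 0.5, `1` = 1, `0` = 2, A = 5, B = 10)
  argos <- NULL
  if (any(surfaced)) {
    idx <- which(surfaced)
    nfix <- sample(1:3, length(idx), replace = TRUE)
    day <- rep(idx, nfix)
    cls <- sample(classes, length(day), replace = TRUE, prob = class_p)
    sc <- err_km[cls]
    argos <- tibble::tibble(
      timestamp = as.POSIXct(track$date[day], tz = "UTC") +
        runif(length(day), 0, 86399),
      lon = track$lon[day] + rnorm(length(day), 0, sc / (KM_PER_DEG * cos(track$lat[day] * pi / 180))),
      lat = track$lat[day] + rnorm(length(day), 0, sc / KM_PER_DEG),
      loc_class = cls
    )
    argos <- argos[order(argos$timestamp), ]
  } else {
    argos <- tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                            lon = numeric(), lat = numeric(),
                            loc_class = character())
  }

  structure(list(animal_id = track$animal_id[1], light = light, argos = argos),
            class = "obs_series")
}

#' Simulate a tagged cohort
#'
#' Convenience wrapper: one environment, `n_animals` deployments staggered
#' around the same summer tagging area, strategies drawn from
#' `config$strategy_mix`, and observations for every animal. All animals are
#' tracked for at least 165 days, mirroring the inclusion rule of keeping
#' only animals tracked into the January after tag attachment.
#'
#' @param config a [sim_config()]; `config$seed` drives everything.
#' @param env optionally, a pre-built `env_fields`; by default a 30 x 34
#'   degree north-east Atlantic-like domain is generated from the same seed.
#' @param n_days days of tracking per animal (default 365, minimum 165).
#' @return list with `env`, `tracks` (list of `true_track`), `obs` (list of
#'   `obs_series`) and `deployments`.
#' @export
simulate_cohort <- function(config = sim_config(), env = NULL, n_days = 365L) {
  stopifnot(n_days >= 165)
  set.seed(as.integer(config$seed))
  if (is.null(env))
    env <- make_environment(c(-28, 2, 30, 64), n_days = n_days + 31L,
                            seed = config$seed)
  n <- config$n_animals
  # allocate strategy counts by largest remainder so the realised mix
  # matches the configured proportions as closely as n allows
  frac <- config$strategy_mix * n
  counts <- floor(frac)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(frac - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  strategies <- sample(rep(names(config$strategy_mix), counts))
  seeds <- sample.int(2^31 - 2, 2 * n)

  deployments <- lapply(seq_len(n), function(i) {
    list(animal_id = sprintf("bs%02d", i),
         date = env$dates[1] + sample(0:14, 1),
         lon = env$extent[2] - 8 + runif(1, -1.5, 1.5),
         lat = 56 + runif(1, -1.5, 1.5))
  })
  tracks <- lapply(seq_len(n), function(i)
    simulate_track(deployments[[i]], strategies[i], env, seed = seeds[i],
                   n_days = n_days))
  obs <- lapply(seq_len(n), function(i)
    simulate_observations(tracks[[i]], env, config, seed = seeds[n + i]))
  list(env = env, tracks = tracks, obs = obs, deployments = deployments,
       strategies = stats::setNames(strategies, vapply(deployments, `[[`, "", "animal_id")))
}

#' Write an observation series to CSV
#'
#' The archival stream goes to `<stem>_light.csv` (columns `date`,
#' `light_lon`, `light_lat`, `sst_c`, `max_depth_m`) and the Argos stream to
#' `<stem>_argos.csv` (`timestamp`, `lon`, `lat`, `loc_class`).
#'
#' @param obs an `obs_series`.
#' @param stem path stem (no extension).
#' @param comment optional comment line (e.g. a config hash) written atop
#'   each file.
#' @return invisibly, the two file paths.
#' @export
write_obs_csv <- function(obs, stem, comment = NULL) {
  paths <- paste0(stem, c("_light.csv", "_argos.csv"))
  for (k in 1:2) {
    df <- if (k == 1) obs$light else obs$argos
    if (!is.null(comment)) {
      writeLines(paste("#", comment), paths[k])
      readr::write_csv(df, paths[k], append = TRUE, col_names = TRUE)
    } else readr::write_csv(df, paths[k])
  }
  invisible(paths)
}

#' @rdname write_obs_csv
#' @param path a `_light.csv` / `_argos.csv` file written by [write_obs_csv()].
#' @export
read_obs_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
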