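#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6,371 km; underlies every
#' straight-line distance and displacement figure in the package.
#'
#' @param p1,p2 numeric `c(lon, lat)` in degrees.
#' @return distance in km.
#' @export
haversine_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = 6371)
}

ARGOS_CLASS_ORDER <- c("3", "2", "1", "0", "A", "B")  # best to worst; Z invalid

#' Forward speed filter for Argos fixes
#'
#' Removes fixes implying implausible travel speed. Class-Z (invalid) fixes
#' are always removed; the first remaining fix is always retained; each later
#' fix is kept only if the great-circle speed from the last retained fix does
#' not exceed `vmax_kmh`. The default 9 km/h is generous for sustained
#' basking-shark swimming.
#'
#' @param fixes tibble with `timestamp` (POSIXct, ordered), `lon`, `lat`,
#'   `loc_class`.
#' @param vmax_kmh maximum plausible speed, km/h.
#' @return the retained subsequence of `fixes`.
#' @export
speed_filter <- function(fixes, vmax_kmh = 9) {
  fixes <- fixes[fixes$loc_class != "Z", , drop = FALSE]
  n <- nrow(fixes)
  if (n == 0) return(fixes)
  keep <- logical(n); keep[1] <- TRUE
  last <- 1L
  for (i in seq_len(n)[-1]) {
    dt_h <- as.numeric(difftime(fixes$timestamp[i], fixes$timestamp[last],
                                units = "hours"))
    d_km <- haversine_km(c(fixes$lon[last], fixes$lat[last]),
                         c(fixes$lon[i], fixes$lat[i]))
    if (dt_h <= 0 || d_km / dt_h <= vmax_kmh) { keep[i] <- TRUE; last <- i }
  }
  fixes[keep, , drop = FALSE]
}

#' Reduce Argos fixes to one location per day
#'
#' For each UTC day, keeps the fix of best location class
#' (3 > 2 > 1 > 0 > A > B); ties within the best class are broken by
#' proximity to 12:00 UTC.
#'
#' @param fixes a (filtered) Argos fix tibble.
#' @param animal_id identifier copied into the output.
#' @return tibble with `animal_id`, `date`, `lon`, `lat`, `source = "argos"`.
#' @export
daily_reduce <- function(fixes, animal_id = NA_character_) {
  if (!nrow(fixes))
    return(tibble::tibble(animal_id = character(), date = as.Date(character()),
                          lon = numeric(), lat = numeric(), source = character()))
  day <- as.Date(fixes$timestamp, tz = "UTC")
  rank <- match(fixes$loc_class, ARGOS_CLASS_ORDER)
  mid_off <- abs(as.numeric(fixes$timestamp) -
                   as.numeric(as.POSIXct(paste(day, "12:00:00"), tz = "UTC")))
  ord <- order(day, rank, mid_off)
  f <- fixes[ord, , drop = FALSE]
  first <- !duplicated(day[ord])
  tibble::tibble(animal_id = animal_id, date = day[ord][first],
                 lon = f$lon[first], lat = f$lat[first], source = "argos")
}

#' Track distance and displacement metrics
#'
#' `along_track_distance()` is the cumulative great-circle distance over
#' consecutive daily locations (the "minimum straight-line along-track
#' distance"). `displacement_stats()` gives the per-day great-circle distance
#' from the deployment location and its maximum. `min_monthly_latitude()`
#' returns the minimum latitude per calendar month.
#'
#' @param track tibble with `date`, `lon`, `lat` (one row per day).
#' @return `along_track_distance`: km (0 with a warning for < 2 locations).
#' @export
along_track_distance <- function(track) {
  n <- nrow(track)
  if (n < 2) { warning("track has fewer than 2 locations"); return(0) }
  sum(geosphere::distHaversine(cbind(track$lon[-n], track$lat[-n]),
                               cbind(track$lon[-1], track$lat[-1]), r = 6371))
}

#' @rdname along_track_distance
#' @param deployment list with `lon`, `lat` of the tagging location.
#' @return `displacement_stats`: list with `series` (tibble `date`,
#'   `displacement_km`) and `max_displacement_km`.
#' @export
displacement_stats <- function(track, deployment) {
  d <- geosphere::distHaversine(cbind(track$lon, track$lat),
                                c(deployment$lon, deployment$lat), r = 6371)
  list(series = tibble::tibble(date = track$date, displacement_km = d),
       max_displacement_km = if (length(d)) max(d) else 0)
}

#' @rdname along_track_distance
#' @return `min_monthly_latitude`: tibble with `month` ("YYYY-MM") and
#'   `min_lat`.
#' @export
min_monthly_latitude <- function(track) {
  m <- format(track$date, "%Y-%m")
  out <- tapply(track$lat, m, min)
  tibble::tibble(month = names(out), min_lat = as.numeric(out))
}

#' Per-animal track summary
#'
#' @param track daily-location tibble.
#' @param deployment tagging location list (`lon`, `lat`).
#' @return one-row tibble: `animal_id`, `n_days`, `along_track_km`,
#'   `max_displacement_km`, `southernmost_lat`.
#' @export
track_summary <- function(track, deployment) {
  tibble::tibble(
    animal_id = track$animal_id[1],
    n_days = nrow(track),
    along_track_km = if (nrow(track) >= 2) along_track_distance(track) else 0,
    max_displacement_km = displacement_stats(track, deployment)$max_displacement_km,
    southernmost_lat = min(track$lat)
  )
}

#' Cohort summary table
#'
#' Median, quartiles (linear interpolation between order statistics),
#' minimum and maximum of each numeric metric across animals.
#'
#' @param summaries tibble of per-animal summaries (e.g. rows from
#'   [track_summary()]).
#' @return tibble with one row per metric: `metric`, `median`, `q25`, `q75`,
#'   `min`, `max`.
#' @export
cohort_summary <- function(summaries) {
  stopifnot(nrow(summaries) >= 1)
  num <- summaries[vapply(summaries, is.numeric, TRUE)]
  rows <- lapply(names(num), function(nm) {
    x <- num[[nm]]
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(metric = nm, median = q[2], q25 = q[1], q75 = q[3],
                   min = min(x), max = max(x))
  })
  dplyr::bind_rows(rows)
}
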