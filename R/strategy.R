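#' Southernmost latitude of a track
#'
#' The most southerly latitude reached, taken over best daily locations; the
#' proxy on which migration strategies are separated.
#'
#' @param track tibble with a `lat` column (>= 1 row).
#' @return minimum latitude, degrees.
#' @export
southernmost_latitude <- function(track) {
  if (!nrow(track)) stop("empty track")
  min(track$lat)
}

#' K-means classification of migration strategies
#'
#' Clusters animals on their southernmost latitude (k-means, Lloyd's
#' algorithm, 25 random restarts under the given seed, best within-cluster
#' sum of squares kept) and relabels the clusters `a`, `b`, `c`, ... in order
#' of decreasing mean southernmost latitude, so that `a` is the
#' shortest-range strategy and `c` the longest. Ties in mean latitude are
#' broken by decreasing cluster size.
#'
#' @param latitudes tibble with `animal_id` and `min_lat`, or a named numeric
#'   vector of southernmost latitudes.
#' @param k number of strategies (default 3).
#' @param seed integer seed (fixes the restarts, hence the output).
#' @return tibble `animal_id`, `min_lat`, `strategy`.
#' @export
kmeans_strategies <- function(latitudes, k = 3, seed = 1L) {
  if (is.numeric(latitudes))
    latitudes <- tibble::tibble(
      animal_id = names(latitudes) %||% as.character(seq_along(latitudes)),
      min_lat = as.numeric(latitudes))
  x <- latitudes$min_lat
  if (k > length(unique(x)))
    stop("k exceeds the number of distinct southernmost latitudes")
  set.seed(as.integer(seed))
  km <- kmeans(matrix(x, ncol = 1), centers = k, nstart = 25,
               algorithm = "Lloyd", iter.max = 100)
  means <- as.numeric(km$centers)
  sizes <- km$size
  ord <- order(-means, -sizes)  # a = northernmost cluster
  relabel <- character(k); relabel[ord] <- letters[seq_len(k)]
  tibble::tibble(animal_id = latitudes$animal_id, min_lat = x,
                 strategy = relabel[km$cluster])
}

DEPTH_BIN_EDGES <- c(0, 25, 50, 100, 200, 500, 750, 1000, Inf)
DEPTH_BIN_LABELS <- c("0-25", "26-50", "51-100", "101-200", "201-500",
                      "501-750", "751-1000", ">1000")

#' Depth-use profile over the standard eight bins
#'
#' Proportion of days whose maximum depth falls in each of the bins
#' 0--25, 26--50, 51--100, 101--200, 201--500, 501--750, 751--1,000 and
#' > 1,000 m. Bins are right-closed ((25, 50] etc., with 0 included in the
#' first), so a boundary value such as 50 m counts in the shallower bin —
#' consistent with the integer-metre bin labels.
#'
#' @param daily_max_depths numeric vector of daily maximum depths, metres
#'   (>= 0).
#' @return named numeric vector of 8 proportions summing to 1.
#' @export
depth_bin_proportions <- function(daily_max_depths) {
  if (any(daily_max_depths < 0, na.rm = TRUE)) stop("negative depth")
  d <- daily_max_depths[!is.na(daily_max_depths)]
  stopifnot(length(d) > 0)
  b <- cut(d, DEPTH_BIN_EDGES, labels = DEPTH_BIN_LABELS,
           include.lowest = TRUE, right = TRUE)
  stats::setNames(as.numeric(table(b)) / length(d), DEPTH_BIN_LABELS)
}

#' Fraction of days in the epipelagic zone
#'
#' Fraction of days with maximum depth within 0--200 m; identically the sum
#' of the first four depth bins.
#'
#' @inheritParams depth_bin_proportions
#' @return fraction in \[0, 1\].
#' @export
epipelagic_fraction <- function(daily_max_depths) {
  d <- daily_max_depths[!is.na(daily_max_depths)]
  mean(d <= 200)
}
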