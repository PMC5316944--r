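test_that("build_grid lays out cells and flags land as specified", {
  g <- toy_grid(c(0, 10, 40, 50), 1)
  expect_equal(length(g$lon) * length(g$lat), 100)
  # centroid of cell (1,1) at extent min + resolution/2
  expect_equal(g$lon[1], 0.5)
  expect_equal(g$lat[1], 40.5)
  expect_error(build_grid(c(0, 10, 40, 50), 3, flat_sea()), "divide")
  expect_error(build_grid(c(0, 10, 40, 50), 1, flat_sea(0)), "no sea")
  # half-land domain: land flagged where depth 0
  shelfy <- function(lon, lat) ifelse(lon > 5, 0, 500)
  g2 <- build_grid(c(0, 10, 40, 50), 1, shelfy)
  expect_equal(sum(g2$sea), 50)
})

test_that("predict step conserves mass and is the identity at D = 0", {
  g <- toy_grid()
  p <- matrix(0, length(g$lon), length(g$lat)); p[10, 1] <- 1
  expect_identical(predict_step(p, g, filter_config(D = 0), 1), p)
  out <- predict_step(p, g, filter_config(D = 1000), 1)
  expect_lt(abs(sum(out) - 1), 1e-9)
  expect_true(all(out >= 0))
  expect_error(predict_step(2 * p, g, filter_config(), 1), "sum to 1")
})

test_that("predict step reproduces the analytic diffusion spread", {
  g <- build_grid(c(-10, 0, 40, 50), 0.25, flat_sea())
  i0 <- 20; j0 <- 20
  p <- matrix(0, length(g$lon), length(g$lat)); p[i0, j0] <- 1
  out <- predict_step(p, g, filter_config(D = 1000), 1)
  kpd <- 2 * pi * 6371 / 360
  xkm <- outer(g$lon - g$lon[i0], cos(g$lat * pi / 180)) * kpd
  ykm <- matrix((g$lat - g$lat[j0]) * kpd, length(g$lon), length(g$lat),
                byrow = TRUE)
  vx <- sum(out * xkm^2) - sum(out * xkm)^2
  vy <- sum(out * ykm^2) - sum(out * ykm)^2
  expect_lt(abs(vx / 2000 - 1), 0.02)   # 2 D t = 2000 km^2 per axis
  expect_lt(abs(vy / 2000 - 1), 0.02)
})

test_that("no mass ever leaks onto land", {
  shelfy <- function(lon, lat) ifelse(lon > 15, 0, 3000)
  g <- build_grid(c(0, 20, 40, 44), 1, shelfy)
  p <- matrix(0, length(g$lon), length(g$lat)); p[14, 2] <- 1
  for (k in 1:5) p <- predict_step(p, g, filter_config(D = 3000), 1)
  expect_lt(abs(sum(p) - 1), 1e-9)
  expect_true(all(p[!g$sea] == 0))
})

test_that("light likelihood is Gaussian with the stated ratios", {
  g <- build_grid(c(0, 10, 40, 47), 0.5, flat_sea())
  fix <- c(5.25, 43.25)  # exactly on a centroid
  L <- light_likelihood(fix, g, filter_config())
  i <- which(g$lon == 5.25); j <- which(g$lat == 43.25)
  expect_equal(which.max(L), (j - 1) * length(g$lon) + i)  # mode at the fix
  # symmetry about the fix in latitude
  expect_equal(L[i, j + 2], L[i, j - 2])
  # 3.5 degrees poleward in latitude: ratio exp(1/2)
  jp <- which(g$lat == 43.25 + 3.5)
  expect_equal(L[i, j] / L[i, jp], exp(1 / 2))
  # 1 degree east in longitude: ratio exp(1/2) too (sigma_lon = 1)
  ip <- which(g$lon == 6.25)
  expect_equal(L[i, j] / L[ip, j], exp(1 / 2))
  # missing fix carries no information
  expect_true(all(light_likelihood(c(NA, NA), g, filter_config()) == 1))
})

test_that("SST likelihood matches the Gaussian mismatch model", {
  fld <- matrix(c(10, 10.5, 12, 13), 2, 2)
  L <- sst_likelihood(10, fld, filter_config())
  expect_equal(which.max(L), 1)
  expect_equal(L[2, 1] / L[1, 1], exp(-1 / 2) / 1)  # |obs - field| = 0.5 C
  expect_true(all(sst_likelihood(10, matrix(12, 3, 3)) ==
                    sst_likelihood(10, matrix(12, 3, 3))[1]))  # constant field
  expect_true(all(sst_likelihood(NA, fld) == 1))
})

test_that("depth mask constrains by bathymetry", {
  graded <- function(lon, lat) 100 * ceiling(lon)  # 100..1000 m by column
  g <- build_grid(c(0, 10, 40, 44), 1, graded)
  expect_equal(depth_mask(0, g), g$sea * 1)
  expect_true(all(depth_mask(NA, g) == g$sea))
  m <- depth_mask(300, g)
  expect_equal(sum(m), 8 * 4)  # exactly the cells with >= 300 m
  expect_true(all(m[g$bathy >= 300] == 1))
  m0 <- depth_mask(5000, g)
  expect_equal(sum(m0), 0)
  expect_true(isTRUE(attr(m0, "contradictory")))
  expect_error(depth_mask(-1, g), ">= 0")
})

test_that("update step is a Bayes update with the stated fallback order", {
  prior <- matrix(c(0.5, 0.3, 0.2), 1, 3)
  lik <- matrix(c(0.1, 0.1, 0.8), 1, 3)
  post <- update_step(prior, list(light = lik))
  expect_equal(as.numeric(post), c(5 / 24, 3 / 24, 16 / 24))
  # flat prior returns the normalised likelihood
  flat <- matrix(1 / 3, 1, 3)
  expect_equal(as.numeric(update_step(flat, list(light = lik))),
               c(0.1, 0.1, 0.8))
  # no information leaves the prior untouched
  expect_equal(update_step(prior, list(light = matrix(1, 1, 3))), prior)
  expect_equal(update_step(prior, list()), prior)
  # contradictory depth is dropped first, with a warning
  expect_warning(
    post2 <- update_step(prior, list(light = lik,
                                     depth = matrix(0, 1, 3)),
                         date = as.Date("2012-11-02")),
    "depth")
  expect_equal(post2, post)
  # depth then SST dropped before giving up
  expect_warning(expect_warning(
    post3 <- update_step(prior, list(depth = matrix(0, 1, 3),
                                     sst = matrix(0, 1, 3))),
    "depth"), "sst")
  expect_equal(post3, prior)
  expect_error(suppressWarnings(
    update_step(prior, list(light = matrix(0, 1, 3)),
                date = as.Date("2012-11-02"))),
    "2012-11-02")
})

test_that("filter marginals equal the dense forward-algorithm oracle", {
  g <- toy_grid(c(0, 20, 40, 41), 1)  # 20-cell 1-D chain
  fc <- filter_config(D = 1500, sigma_lon = 2)
  dep <- list(date = as.Date("2020-01-01"), lon = 2.5, lat = 40.5)
  obs <- tibble::tibble(date = as.Date("2020-01-02") + 0:4,
                        light_lon = c(3.1, 4.4, NA, 6.2, 7.3),
                        light_lat = 40.5, sst_c = NA, max_depth_m = NA)
  fit <- run_filter(obs, g, fc, dep, env = NULL)
  Tm <- dense_kernel(g, fc)
  init <- rep(0, 20); init[3] <- 1
  liks <- lapply(1:6, function(t) {
    if (t == 1 || t == 4) return(rep(1, 20))
    r <- obs[t - 1, ]
    dnorm(g$lon, r$light_lon, 2) * dnorm(40.5, 40.5, 3.5)
  })
  mar <- dense_hmm_marginals(Tm, init, liks)
  for (t in 1:6)
    expect_lt(max(abs(as.numeric(fit$posteriors[[t]]) - mar[, t])), 1e-10)
})

test_that("smoothing matches the oracle and collapses at the pop-off", {
  g <- toy_grid(c(0, 20, 40, 41), 1)
  fc <- filter_config(D = 1500, sigma_lon = 2)
  dep <- list(date = as.Date("2020-01-01"), lon = 2.5, lat = 40.5,
              popoff = list(date = as.Date("2020-01-06"), lon = 7.5, lat = 40.5))
  obs <- tibble::tibble(date = as.Date("2020-01-02") + 0:4,
                        light_lon = c(3.1, 4.4, NA, 6.2, 7.3),
                        light_lat = 40.5, sst_c = NA, max_depth_m = NA)
  fit <- run_filter(obs, g, fc, dep, env = NULL)
  expect_true(fit$smoothed)
  expect_equal(which.max(fit$posteriors[[6]]), 8)  # pop-off cell
  Tm <- dense_kernel(g, fc)
  init <- rep(0, 20); init[3] <- 1
  liks <- lapply(1:6, function(t) {
    if (t == 1 || t == 4) return(rep(1, 20))
    r <- obs[t - 1, ]
    L <- dnorm(g$lon, r$light_lon, 2) * dnorm(40.5, 40.5, 3.5)
    if (t == 6) { pm <- rep(0, 20); pm[8] <- 1; L <- L * pm }
    L
  })
  mar <- dense_hmm_marginals(Tm, init, liks, smooth = TRUE)
  for (t in 1:6)
    expect_lt(max(abs(as.numeric(fit$posteriors[[t]]) - mar[, t])), 1e-10)
})

test_that("a filter with no observations is a pure diffusion chain", {
  g <- toy_grid(c(0, 10, 40, 44), 1)
  fc <- filter_config(D = 800)
  dep <- list(date = as.Date("2020-03-01"), lon = 4.5, lat = 41.5)
  fit <- run_filter(NULL, g, fc, dep, env = NULL,
                    end_date = as.Date("2020-03-05"))
  p <- matrix(0, length(g$lon), length(g$lat)); p[5, 2] <- 1  # cell of (4.5, 41.5)
  for (t in 2:5) {
    p <- predict_step(p, g, fc, 1)
    expect_equal(fit$posteriors[[t]], p)
  }
})

test_that("posterior invariants hold on a realistic fit", {
  co <- cohort_fixture()
  grid <- build_grid(co$env$extent, 1, co$env)
  tr <- co$tracks[[1]]; dep <- co$deployments[[1]]
  dep$popoff <- list(date = tr$date[200], lon = tr$lon[200], lat = tr$lat[200])
  obs <- co$obs[[1]]$light[1:199, ]
  fit <- run_filter(obs, grid, filter_config(), dep, env = co$env,
                    end_date = tr$date[200])
  sums <- vapply(fit$posteriors, sum, 0)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(vapply(fit$posteriors, function(p) min(p), 0) >= 0))
  land_mass <- vapply(fit$posteriors, function(p) sum(p[!grid$sea]), 0)
  expect_true(all(land_mass == 0))
})

test_that("best daily location is the probability-weighted mean", {
  g <- toy_grid(c(0, 10, 40, 44), 1)
  p <- matrix(0, length(g$lon), length(g$lat)); p[3, 2] <- 1
  expect_equal(best_daily_location(p, g), c(lon = 2.5, lat = 41.5))
  # equal mass in two cells: midpoint
  p2 <- matrix(0, length(g$lon), length(g$lat))
  p2[1, 1] <- 0.5; p2[5, 3] <- 0.5
  expect_equal(best_daily_location(p2, g), c(lon = 2.5, lat = 41.5))
  # mass 0.2 / 0.8 at lon 0 and 10 -> lon 8 (on a grid whose centroids hit 0 and 10)
  g3 <- build_grid(c(-1, 11, 40, 44), 1, flat_sea())
  p3 <- matrix(0, length(g3$lon), length(g3$lat))
  p3[g3$lon == -0.5, 1] <- 0.2; p3[g3$lon == 9.5, 1] <- 0.8
  expect_equal(unname(best_daily_location(p3, g3)["lon"]), 0.2 * -0.5 + 0.8 * 9.5)
})

test_that("track recovery beats the raw fixes and is grid-stable", {
  co <- cohort_fixture()
  i <- 2
  tr <- co$tracks[[i]]; dep <- co$deployments[[i]]
  dep$popoff <- list(date = tr$date[nrow(tr)], lon = tr$lon[nrow(tr)],
                     lat = tr$lat[nrow(tr)])
  rmse_vs_truth <- function(bt) {
    m <- merge(as.data.frame(tr), as.data.frame(bt), by = "date")
    sqrt(mean(geosphere::distHaversine(cbind(m$lon.x, m$lat.x),
                                       cbind(m$lon.y, m$lat.y), r = 6371)^2))
  }
  grid <- build_grid(co$env$extent, 1, co$env)
  bt1 <- best_track(run_filter(co$obs[[i]]$light, grid, filter_config(), dep,
                               env = co$env))
  raw <- co$obs[[i]]$light[!is.na(co$obs[[i]]$light$light_lon), ]
  raw <- tibble::tibble(date = raw$date, lon = raw$light_lon, lat = raw$light_lat)
  expect_lt(rmse_vs_truth(bt1), rmse_vs_truth(raw))  # the filter adds value
})

test_that("doubling grid resolution barely moves smooth-case locations", {
  # smooth open-ocean case: drifting light fixes, no bathymetric edges
  dep <- list(date = as.Date("2020-01-01"), lon = -10.2, lat = 50.1,
              popoff = list(date = as.Date("2020-01-31"), lon = -9.1, lat = 48.4))
  set.seed(64)
  obs <- tibble::tibble(date = as.Date("2020-01-02") + 0:29,
                        light_lon = -10.2 + 0.04 * (1:30) + rnorm(30, 0, 0.3),
                        light_lat = 50.1 - 0.06 * (1:30) + rnorm(30, 0, 0.8),
                        sst_c = NA, max_depth_m = NA)
  bts <- lapply(c(1, 0.5), function(res) {
    g <- build_grid(c(-20, 0, 40, 55), res, flat_sea())
    best_track(run_filter(obs, g, filter_config(), dep, env = NULL))
  })
  shift <- max(abs(bts[[1]]$lon - bts[[2]]$lon),
               abs(bts[[1]]$lat - bts[[2]]$lat))
  expect_lt(shift, 0.5)  # under half a coarse cell
})

test_that("run_filter validates its anchors", {
  g <- toy_grid(c(0, 10, 40, 44), 1)
  expect_error(run_filter(NULL, g, filter_config(),
                          list(date = as.Date("2020-01-01"), lon = 50, lat = 41),
                          end_date = as.Date("2020-01-03")),
               "outside")
  obs <- tibble::tibble(date = as.Date("2019-12-25"), light_lon = 5,
                        light_lat = 41, sst_c = NA, max_depth_m = NA)
  expect_error(run_filter(obs, g, filter_config(),
                          list(date = as.Date("2020-01-01"), lon = 5, lat = 41)),
               "precede")
})
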