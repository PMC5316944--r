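# Shared fixtures: idealised domains and a small cached cohort.

# uniform-depth open ocean (function-based bathymetry field)
flat_sea <- function(depth_m = 3000) function(lon, lat) rep(depth_m, length(lon))

# small all-sea grid helper
toy_grid <- function(extent = c(0, 20, 40, 41), res = 1, depth = 3000) {
  build_grid(extent, res, flat_sea(depth))
}

# dense transition matrix of the movement kernel on a grid (treats the
# flattened [lon, lat] field as the state vector); oracle building block
dense_kernel <- function(grid, config, dt = 1) {
  n <- length(grid$lon) * length(grid$lat)
  sapply(seq_len(n), function(k) {
    e <- matrix(0, length(grid$lon), length(grid$lat))
    e[k] <- 1
    as.numeric(predict_step(e, grid, config, dt))
  })
}

# brute-force dense HMM forward(-backward) marginals; independent of
# run_filter's recursion. liks: list of length T of flattened fields
# (lik[[1]] ignored, day 1 is the deployment point mass).
dense_hmm_marginals <- function(Tm, init, liks, smooth = FALSE) {
  Tn <- length(liks)
  n <- length(init)
  alpha <- matrix(0, n, Tn)
  alpha[, 1] <- init
  for (t in seq_len(Tn)[-1]) {
    a <- as.numeric(Tm %*% alpha[, t - 1]) * liks[[t]]
    alpha[, t] <- a / sum(a)
  }
  if (!smooth) return(alpha)
  beta <- matrix(1, n, Tn)
  for (t in rev(seq_len(Tn - 1))) {
    b <- as.numeric(t(Tm) %*% (liks[[t + 1]] * beta[, t + 1]))
    beta[, t] <- b / sum(b)
  }
  g <- alpha * beta
  sweep(g, 2, colSums(g), "/")
}

# one modest cohort, simulated once per test run and reused
cohort_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_config(seed = 99, n_animals = 4),
                                n_days = 300)
    cache
  }
})
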