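# shared fixtures: small rasters and fast MCMC settings

flat_dem <- function(n = 8, value = 100, cell = 3) {
  terra_raster(matrix(value, n, n), cell_size = cell)
}

# inclined plane; slope_deg downslope towards `facing` ("south" or "north")
plane_dem <- function(n = 12, slope_deg = 30, facing = "south", cell = 3) {
  rise <- tan(slope_deg * pi / 180) * cell
  rows <- matrix(seq_len(n), n, n)
  v <- if (facing == "south") (n - rows) * rise else rows * rise
  terra_raster(v + 100, cell_size = cell)
}

quick_mcmc <- function(seed = 1, chains = 2, iterations = 3000,
                       burn_in = 1500, thin = 3) {
  mcmc_config(chains, iterations, burn_in, thin, seed)
}

# independent brute-force marginal likelihood (direct truncated sum)
brute_site_loglik <- function(y, lambda, p, n_max = 500, phi = 0) {
  keep <- !is.na(y)
  y <- y[keep]; p <- rep_len(p, length(keep))[keep]
  tot <- 0
  for (N in 0:n_max) {
    term <- dpois(N, lambda)
    for (j in seq_along(y)) term <- term * dbinom(y[j], N, p[j])
    tot <- tot + term
  }
  if (phi > 0) tot <- phi * as.numeric(all(y == 0)) + (1 - phi) * tot
  log(tot)
}
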