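test_that("landscape generation is seeded, degenerates flat, and has real relief", {
  a <- generate_landscape(c(64, 64), 3, seed = 5)
  b <- generate_landscape(c(64, 64), 3, seed = 5)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, generate_landscape(c(64, 64), 3, seed = 6)$values))

  flat <- generate_landscape(c(64, 64), 3, roughness = 0, seed = 1)
  expect_lt(diff(range(flat$values)), 1e-12)

  d <- generate_landscape(c(128, 128), 3, seed = 2)
  tv <- tpi(d, 90)$values
  expect_lt(min(tv), 0)
  expect_gt(max(tv), 0)
  expect_error(generate_landscape(c(32, 64)), "64")
})

test_that("plot placement respects the minimum-spacing design", {
  dem <- terra_raster(matrix(0, 500, 500), cell_size = 3) # 1500 m x 1500 m
  pts <- sample_plots(dem, study_design(135, 7, 3, 75), seed = 3)
  expect_equal(nrow(pts), 135)
  expect_gte(min(dist(cbind(pts$x, pts$y))), 75)
  expect_identical(pts, sample_plots(dem, study_design(135, 7, 3, 75), seed = 3))

  one <- sample_plots(dem, study_design(1, 1, 3, 0), seed = 1)
  expect_equal(nrow(one), 1)

  tiny <- terra_raster(matrix(0, 64, 64), cell_size = 1) # 64 m across
  expect_error(sample_plots(tiny, study_design(2, 1, 3, 1e4), seed = 1,
                            max_attempts = 200),
               "could not place")
})

test_that("latent population follows the log-linear Poisson hierarchy", {
  S <- 10000
  X <- tibble::tibble(NDVI = rep(0, S), TPI = rep(0, S), TWI = rep(0, S),
                      PRR = rep(0, S))
  lat <- simulate_population(X, truth_params(), seed = 2)
  expect_equal(unique(lat$lambda), exp(0.445), tolerance = 1e-12)

  allzero <- simulate_population(X, truth_params(phi = 1), seed = 2)
  expect_true(all(allzero$N == 0))

  # Monte Carlo mean of N vs analytic mean(lambda) with Table-1 slopes
  set.seed(77)
  Xr <- tibble::as_tibble(lapply(
    stats::setNames(1:4, c("NDVI", "TPI", "TWI", "PRR")),
    function(i) as.numeric(scale(rnorm(S)))))
  lat <- simulate_population(Xr, truth_params(), seed = 4)
  mc_se <- sd(lat$N) / sqrt(S)
  expect_lt(abs(mean(lat$N) - mean(lat$lambda)), 3 * mc_se)

  # stage counts partition N
  expect_true(all(lat$n_juvenile + lat$n_adult_male + lat$n_female_nongravid +
                    lat$n_gravid == lat$N))

  bad <- X
  bad$NDVI <- rnorm(S, 5, 3)
  expect_error(simulate_population(bad, truth_params(), 1), "not standardized")
})

test_that("survey counts follow the binomial detection layer", {
  # intercept-only detection at the fitted value: logit^-1(-1.64) = 0.163
  S <- 3000
  lat <- tibble::tibble(site_id = sprintf("site_%03d", 1:S),
                        lambda = 5, N = 5L, n_juvenile = 0L, n_adult_male = 5L,
                        n_female_nongravid = 0L, n_gravid = 0L)
  W <- tidyr::expand_grid(survey = 1:2, site_id = lat$site_id)
  tr <- truth_params(alpha = c("(Intercept)" = -1.64), sigma_p = 0)
  ds <- simulate_surveys(lat, W, tr, seed = 5)
  expect_true(all(ds$y <= 5))
  phat <- mean(ds$y) / 5
  se <- sqrt(plogis(-1.64) * (1 - plogis(-1.64)) / (5 * length(ds$y)))
  expect_lt(abs(phat - plogis(-1.64)), 3 * se)

  # mean count near N p = 2.5 at p = 0.5
  tr2 <- truth_params(alpha = c("(Intercept)" = 0), sigma_p = 0)
  ds2 <- simulate_surveys(lat[1:2000, ], W[W$site_id %in% lat$site_id[1:2000], ],
                          tr2, seed = 6)
  se2 <- sqrt(5 * 0.25 / length(ds2$y))
  expect_lt(abs(mean(ds2$y) - 2.5), 3 * se2)

  # p = 0: every count and state code is zero
  ds0 <- simulate_surveys(lat, W, truth_params(alpha = c("(Intercept)" = -40),
                                               sigma_p = 0), seed = 7)
  expect_true(all(ds0$y == 0))
  expect_true(all(ds0$states$gravid == 0))
  expect_true(all(ds0$states$juvenile == 0))
})

test_that("state codes are consistent with counts and stage composition", {
  sim <- simulate_study(study_design(60, 5), seed = 21)
  y <- sim$data$y
  for (st in sim$data$states) {
    expect_true(all(st[y == 0] == 0))
    expect_true(all(st[y > 0] %in% 1:2))
  }
  # cohort cannot be detected where the site holds none
  none <- sim$latents$site_id[sim$latents$n_gravid == 0]
  expect_true(all(sim$data$states$gravid[none, ] != 2))
})

test_that("the study generator is deterministic end to end", {
  a <- simulate_study(study_design(40, 4), seed = 9)
  b <- simulate_study(study_design(40, 4), seed = 9)
  expect_identical(a$data$y, b$data$y)
  expect_identical(a$latents, b$latents)
  expect_false(identical(a$data$y, simulate_study(study_design(40, 4), seed = 10)$data$y))
})

test_that("quadratics and interactions are formed from standardized linear terms", {
  d <- tibble::tibble(a = c(-1, 0, 1), b = c(1, 0, -1))
  m <- build_design_matrix(d, c("(Intercept)", "a", "a^2", "a:b"))
  expect_equal(unname(m[, "a^2"]), d$a^2)
  expect_equal(unname(m[, "a:b"]), d$a * d$b)
  expect_error(build_design_matrix(d, "zzz"), "missing covariate")
})
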