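test_that("marginal likelihood matches closed forms and the brute-force sum", {
  # perfect detection, all-zero counts: only N = 0 survives, log L = -lambda
  expect_equal(marginal_site_loglik(c(0, 0), 2, c(1, 1), n_max = 60), -2)
  # unequal counts under perfect detection are impossible
  expect_equal(marginal_site_loglik(c(3, 1), 2, c(1, 1), n_max = 60), -Inf)

  set.seed(31)
  for (k in 1:25) {
    J <- sample(2:5, 1)
    lam <- runif(1, 0.3, 6)
    p <- runif(J, 0.05, 0.95)
    y <- rpois(J, lam * p)
    phi <- sample(c(0, runif(1, 0.1, 0.6)), 1)
    expect_equal(marginal_site_loglik(y, lam, p, n_max = 500, phi = phi),
                 brute_site_loglik(y, lam, p, n_max = 500, phi = phi),
                 tolerance = 1e-10)
  }

  # truncation-insensitive once n_max clears lambda + 10 sqrt(lambda) + max(y)
  y <- c(1, 2); lam <- 2
  expect_lt(abs(marginal_site_loglik(y, lam, 0.5, n_max = 60) -
                  marginal_site_loglik(y, lam, 0.5, n_max = 500)), 1e-10)
  # ZIP with phi = 0 is exactly the plain Poisson likelihood
  expect_identical(marginal_site_loglik(y, lam, 0.5, 100, phi = 0),
                   marginal_site_loglik(y, lam, 0.5, 100))
  expect_error(marginal_site_loglik(c(-1, 0), 1, 0.5), "nonnegative")
})

test_that("Gelman-Rubin follows its defining formula", {
  expect_equal(gelman_rubin(list(1:100, 1:100)), sqrt(99 / 100), tolerance = 1e-12)
  expect_equal(gelman_rubin(list(c(1, 2, 3), c(4, 5, 6))), sqrt(31 / 6),
               tolerance = 1e-12)
  set.seed(8)
  expect_lt(abs(gelman_rubin(list(rnorm(20000), rnorm(20000))) - 1), 0.01)
  expect_error(gelman_rubin(list(1:3)), "2 chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "equal length")
})

test_that("MCMC fits are reproducible and recover a known intercept model", {
  tr <- truth_params(beta = c("(Intercept)" = log(2)),
                     alpha = c("(Intercept)" = -1.64), sigma_p = 0)
  sim <- simulate_study(study_design(120, 6), tr, seed = 12)
  spec <- nmix_spec()
  mc <- mcmc_config(3, 8000, 4000, 4, seed = 4)
  f1 <- nmix_fit(sim$data, spec, mc)
  f2 <- nmix_fit(sim$data, spec, mc)
  expect_identical(f1$draws, f2$draws)

  td <- tidy(f1)
  pd <- td[td$parameter == "mean_detection", ]
  expect_lt(abs(pd$mean - plogis(-1.64)), 0.06)
  b0 <- td[td$parameter == "beta[(Intercept)]", ]
  expect_true(b0$lower < log(2) && log(2) < b0$upper)
  expect_true(all(td$lower <= td$mean & td$mean <= td$upper))
  expect_true(all(td$rhat >= sqrt((nrow(f1$chains[[1]]) - 1) / nrow(f1$chains[[1]]))))
})

test_that("posterior predictive check flags gross overdispersion", {
  tr <- truth_params(beta = c("(Intercept)" = log(2)),
                     alpha = c("(Intercept)" = -0.5), sigma_p = 0)
  sim <- simulate_study(study_design(100, 5), tr, seed = 13)
  y <- sim$data$y
  # well specified: moderate Bayesian p-value
  f <- nmix_fit(sim$data, nmix_spec(), quick_mcmc(seed = 5))
  expect_gt(f$bayes_p, 0.1)
  expect_lt(f$bayes_p, 0.9)
  # corrupt with heavy clumping -> plain Poisson should fail the check
  y2 <- y
  set.seed(99)
  hot <- sample(nrow(y2), 25)
  y2[hot, ] <- y2[hot, ] + rpois(length(hot) * ncol(y2), 6)
  d2 <- survey_dataset(y2, X = sim$data$X, W = sim$data$W)
  f2 <- nmix_fit(d2, nmix_spec(), quick_mcmc(seed = 6))
  expect_lt(f2$bayes_p, 0.05)
})

test_that("abundance projection averages exp(linear predictor) over draws", {
  terms <- c("(Intercept)", "NDVI", "TPI")
  set.seed(15)
  draws <- cbind(rnorm(200, 0.4, 0.2), rnorm(200, 0.4, 0.1), rnorm(200, -0.3, 0.1))
  colnames(draws) <- paste0("beta[", terms, "]")
  fake <- structure(list(draws = draws,
                         spec = nmix_spec(terms, "(Intercept)")),
                    class = "nmix_fit")
  g <- matrix(rnorm(16), 4, 4)
  rs <- list(NDVI = terra_raster(g, 3), TPI = terra_raster(matrix(rnorm(16), 4, 4), 3))
  out <- predict_abundance(fake, rs)
  # oracle at a handful of pixels
  for (px in c(1, 5, 11)) {
    x <- c(1, as.vector(rs$NDVI$values)[px], as.vector(rs$TPI$values)[px])
    expect_equal(as.vector(out$values)[px], mean(exp(draws %*% x)), tolerance = 1e-10)
  }
  # beta draws all zero -> a raster of ones
  fake0 <- fake
  fake0$draws[] <- 0
  expect_true(all(abs(predict_abundance(fake0, rs)$values - 1) < 1e-12))
  # centred pixel at the fitted intercept posterior
  rs0 <- list(NDVI = terra_raster(matrix(0, 2, 2), 3),
              TPI = terra_raster(matrix(0, 2, 2), 3))
  expect_equal(unname(predict_abundance(fake, rs0)$values[1, 1]),
               mean(exp(draws[, 1])), tolerance = 1e-10)
})

test_that("ZIP fits expose the inflation weight and respect its generating value", {
  tr <- truth_params(beta = c("(Intercept)" = log(4)),
                     alpha = c("(Intercept)" = 0.5), sigma_p = 0, phi = 0.4)
  sim <- simulate_study(study_design(150, 5), tr, seed = 17)
  f <- nmix_fit(sim$data, nmix_spec(family = "zip"), quick_mcmc(seed = 7))
  ph <- tidy(f)
  ph <- ph[ph$parameter == "phi", ]
  expect_true(ph$lower < 0.4 && 0.4 < ph$upper)
  expect_gt(ph$mean, 0.2)
})
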