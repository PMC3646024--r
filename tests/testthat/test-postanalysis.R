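test_that("plot abundance converts to density linearly", {
  expect_equal(round(density_from_abundance(1.968, 9), 3), 0.219)
  expect_equal(round(density_from_abundance(7.869, 9), 3), 0.874)
  expect_equal(density_from_abundance(9, 9), 1)
  a <- c(0.5, 2.3); b <- c(1.1, 0.4)
  expect_equal(density_from_abundance(a + b),
               density_from_abundance(a) + density_from_abundance(b))
  expect_error(density_from_abundance(1, 0), "positive")
})

test_that("regression summary equals the normal-equations oracle", {
  x <- c(1, 2, 3, 4); y <- c(1.1, 1.9, 3.2, 3.8)
  got <- regression_summary(x, y)
  # independent matrix-algebra oracle
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  Fo <- (r2 / 1) / ((1 - r2) / (length(x) - 2))
  expect_equal(got$intercept, beta[1], tolerance = 1e-12)
  expect_equal(got$slope, beta[2], tolerance = 1e-12)
  expect_equal(got$r_squared, r2, tolerance = 1e-12)
  expect_equal(got$statistic, Fo, tolerance = 1e-10)
  expect_equal(got$p_value, pf(Fo, 1, 2, lower.tail = FALSE), tolerance = 1e-12)

  # exact fit: R^2 = 1
  ex <- regression_summary(x, 2 * x)
  expect_equal(ex$r_squared, 1)
  expect_equal(ex$p_value, 0)

  # jointly permuting pairs changes nothing
  perm <- c(3, 1, 4, 2)
  expect_equal(regression_summary(x[perm], y[perm]), got)

  # alternative denominator convention
  alt <- regression_summary(x, y, df_convention = "n_minus_1")
  expect_equal(alt$df2, 3L)
  expect_gt(alt$statistic, got$statistic)

  expect_error(regression_summary(c(1, 1, 1), y[1:3]), "constant")
  expect_error(regression_summary(x[1:2], y[1:2]), "at least 3")
})

test_that("slope interaction test is exact under identical groups", {
  x <- rep(seq(0, 1, length.out = 20), 2)
  y <- rep(0.3 + 0.5 * seq(0, 1, length.out = 20) + rep(0, 20), 2)
  g <- rep(c("a", "b"), each = 20)
  out <- slope_interaction_test(x, y, g)
  expect_equal(out$estimate, 0, tolerance = 1e-12)
  expect_error(slope_interaction_test(x, y, rep("a", 40)), "2 levels")
})

test_that("cohort landscape summary joins, regresses, and guards inputs", {
  set.seed(33)
  n <- 40
  ids <- sprintf("site_%03d", 1:n)
  temp <- rnorm(n, 28, 2)
  ab <- tibble::tibble(site_id = ids, mean = exp(1 - 0.2 * scale(temp)[, 1] + rnorm(n, 0, 0.2)))
  juv <- tibble::tibble(site_id = ids, R_hat = plogis(0.5 - 0.9 * scale(temp)[, 1]))
  gra <- tibble::tibble(site_id = ids, R_hat = plogis(rnorm(n, 1.08, 0.05)))
  tmp <- tibble::tibble(site_id = ids, temp_c = temp)
  out <- cohort_landscape_summary(ab, gra, juv, tmp)
  expect_equal(nrow(out$table), n)
  expect_equal(nrow(out$regressions), 5)
  jt <- out$regressions[out$regressions$regression == "juvenile_vs_temperature", ]
  expect_lt(jt$slope, 0)
  expect_equal(nrow(out$interactions), 2)

  expect_error(cohort_landscape_summary(ab[1:2, ], gra[1:2, ], juv[1:2, ], tmp[1:2, ]),
               "at least 3")
  bad <- tmp; bad$site_id[1] <- "zzz"
  expect_error(cohort_landscape_summary(ab, gra, juv, bad), "orphans")
})
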