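test_that("history probabilities are a proper distribution over all histories", {
  set.seed(23)
  for (rep in 1:4) {
    th <- runif(5)
    for (J in 1:4) {
      hists <- as.matrix(expand.grid(rep(list(0:2), J)))
      tot <- sum(apply(hists, 1, function(o)
        history_probability(o, th[1], th[2], th[3], th[4], th[5])))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("history probability matches hand products and latent-state enumeration", {
  expect_equal(history_probability(2, 1, 1, 0.5, 1, 1), 1)
  expect_equal(history_probability(2, 0.8, 0.747, 0.5, 0.5, 0.46),
               0.8 * 0.747 * 0.5 * 0.46, tolerance = 1e-12)
  # two-survey history (1, 2): explicit enumeration over the 3 latent states
  psi <- 0.7; R <- 0.55; p1 <- 0.3; p2 <- 0.45; del <- 0.4
  by_state <- (1 - psi) * 0 +                       # unoccupied cannot yield 1
    psi * (1 - R) * (p1 * 0) +                      # state 1 cannot yield 2
    psi * R * (p2 * (1 - del)) * (p2 * del)
  expect_equal(history_probability(c(1, 2), psi, R, p1, p2, del), by_state,
               tolerance = 1e-12)
  # missing surveys drop out
  expect_equal(history_probability(c(1, NA, 2), psi, R, p1, p2, del), by_state,
               tolerance = 1e-12)
  expect_error(history_probability(c(0, 3), 0.5, 0.5, 0.5, 0.5, 0.5), "codes")
})

test_that("likelihood is invariant to survey permutation with constant detection", {
  obs <- simulate_multistate(40, 5, seed = 2)
  ll <- function(o) sum(log(apply(o, 1, history_probability,
                                  psi = 0.6, R = 0.5, p1 = 0.4, p2 = 0.4,
                                  delta = 0.35)))
  expect_equal(ll(obs), ll(obs[, c(3, 1, 5, 2, 4)]), tolerance = 1e-12)
})

test_that("with delta and R pinned at 1 the model is two-state occupancy", {
  obs <- simulate_multistate(60, 5, psi = 0.6, R = 1, p2 = 0.45, delta = 1,
                             seed = 4)
  m <- fit_multistate(obs, fix = list(R = 1, delta = 1), seed = 1)
  # hand-written single-season occupancy log-likelihood at the fitted point
  th <- m$estimates$estimate
  psi <- plogis(th[m$idx$psi]); p <- plogis(th[m$idx$p])
  det <- rowSums(obs == 2)
  J <- ncol(obs)
  ll2 <- sum(log(ifelse(det == 0,
                        (1 - psi) + psi * (1 - p)^J,
                        psi * p^det * (1 - p)^(J - det))))
  expect_equal(m$logLik, ll2, tolerance = 1e-8)
})

test_that("the MLE dominates the generating truth and is deterministic", {
  truth <- c(psi = 0.7, R = 0.6, p = 0.45, delta = 0.4)
  for (sd in 1:4) {
    obs <- simulate_multistate(135, 7, truth["psi"], truth["R"], truth["p"],
                               truth["p"], truth["delta"], seed = sd)
    m <- fit_multistate(obs, seed = 1)
    ll_truth <- sum(log(apply(obs, 1, history_probability, psi = truth["psi"],
                              R = truth["R"], p1 = truth["p"], p2 = truth["p"],
                              delta = truth["delta"])))
    expect_gte(m$logLik, ll_truth)
  }
  obs <- simulate_multistate(80, 6, seed = 9)
  m1 <- fit_multistate(obs, seed = 3)
  m2 <- fit_multistate(obs, seed = 3)
  expect_identical(m1$estimates, m2$estimates)
})

test_that("conditional occurrence applies the inverse logit with a delta-method band", {
  fake <- structure(list(
    estimates = tibble::tibble(block = "R", term = "(Intercept)",
                               estimate = 1.083, se = 0.03, boundary = FALSE),
    idx = list(R = 1L), blocks = list(R = "(Intercept)"),
    design = list(XR = matrix(1, 3, 1)),
    vcov = matrix(0.0009), site_ids = c("a", "b", "c")),
    class = "multistate_fit")
  co <- conditional_occurrence(fake)
  expect_equal(co$R_hat, rep(plogis(1.083), 3), tolerance = 1e-12)
  expect_equal(round(co$R_hat[1], 3), 0.747)
  expect_true(all(co$lower < co$R_hat & co$R_hat < co$upper))

  # one-covariate fit: the band widens away from the covariate centre
  fake2 <- structure(list(
    estimates = tibble::tibble(block = "R", term = c("(Intercept)", "x"),
                               estimate = c(0.2, 0.5), se = 0.1,
                               boundary = FALSE),
    idx = list(R = 1:2), blocks = list(R = c("(Intercept)", "x")),
    design = list(XR = cbind(1, c(-2, -0.5, 0, 0.5, 2))),
    vcov = diag(c(0.01, 0.01)),
    site_ids = sprintf("s%d", 1:5)), class = "multistate_fit")
  co2 <- conditional_occurrence(fake2)
  logit_width <- qlogis(co2$upper) - qlogis(co2$lower)
  expect_true(logit_width[1] > logit_width[2])
  expect_true(logit_width[5] > logit_width[4])
  expect_true(which.min(logit_width) == 3)
})
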