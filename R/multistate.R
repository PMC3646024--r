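#' Probability of one site's 0/1/2 detection history
#'
#' Conditional binomial parameterization of the three-state occupancy
#' model. Latent states: unoccupied (prob `1 - psi`); occupied without the
#' target cohort (`psi (1 - R)`); occupied with the cohort (`psi R`).
#' Observation model per survey: state 1 gives code 1 with probability
#' `p1` (code 2 impossible); state 2 gives code 2 with probability
#' `p2 delta`, code 1 with `p2 (1 - delta)`. Missing surveys (NA)
#' contribute nothing.
#'
#' @param obs_i integer vector of codes 0/1/2 over surveys (NA allowed).
#' @param psi occupancy probability.
#' @param R conditional probability the cohort is present given occupancy.
#' @param p1 detection probability in state 1 (scalar or per survey).
#' @param p2 detection probability in state 2 (scalar or per survey).
#' @param delta probability a detection in state 2 includes the cohort.
#' @return the history probability.
#' @export
history_probability <- function(obs_i, psi, R, p1, p2, delta) {
  if (any(!is.na(obs_i) & !obs_i %in% 0:2)) {
    stop("observation codes must be 0, 1 or 2.", call. = FALSE)
  }
  keep <- !is.na(obs_i)
  o <- obs_i[keep]
  J <- length(obs_i)
  p1 <- rep_len(p1, J)[keep]; p2 <- rep_len(p2, J)[keep]
  delta <- rep_len(delta, J)[keep]
  f1 <- ifelse(o == 0, 1 - p1, ifelse(o == 1, p1, 0))
  f2 <- ifelse(o == 0, 1 - p2, ifelse(o == 1, p2 * (1 - delta), p2 * delta))
  allzero <- all(o == 0)
  (1 - psi) * allzero + psi * (1 - R) * prod(f1) + psi * R * prod(f2)
}

ms_design <- function(data, terms, n) {
  if (is.null(data)) {
    if (!identical(terms, "(Intercept)")) {
      stop("covariate terms given but no covariate table supplied.", call. = FALSE)
    }
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  build_design_matrix(data, terms)
}

#' Fit a three-state multistate occupancy model by maximum likelihood
#'
#' Sums the log history probabilities over sites and maximizes by
#' quasi-Newton (BFGS) from multiple seeded starts. All parameters are on
#' the logit scale; covariates enter `psi`, `R` and `p` via the usual
#' design-matrix terms. By default the two occupied states share one
#' detection probability (`p1 = p2`), with `delta` carrying the extra
#' cohort-detection layer; `p_shared = FALSE` frees them. `fix` pins a
#' probability parameter (e.g. `fix = list(R = 1, delta = 1)` collapses
#' the model to single-season two-state occupancy). Standard errors come
#' from the inverse observed information; boundary estimates are flagged
#' and their SEs reported as NA.
#'
#' @param obs S x J matrix of 0/1/2 codes (rownames = site ids; NA
#'   allowed).
#' @param X site covariate tibble (`site_id` + standardized columns), for
#'   `psi_terms` / `R_terms`.
#' @param W long survey covariate tibble (`site_id`, `survey`, columns),
#'   for `p_terms`.
#' @param psi_terms,R_terms,p_terms,delta_terms model terms per parameter.
#' @param p_shared single detection probability for both occupied states.
#' @param fix named list of probabilities to pin (among `psi`, `R`, `p1`,
#'   `p2`, `delta`).
#' @param n_starts number of seeded optimizer starts (>= 1).
#' @param seed integer seed for the start values.
#' @return a `multistate_fit`.
#' @export
fit_multistate <- function(obs, X = NULL, W = NULL,
                           psi_terms = "(Intercept)", R_terms = "(Intercept)",
                           p_terms = "(Intercept)", delta_terms = "(Intercept)",
                           p_shared = TRUE, fix = list(), n_starts = 5, seed = 1) {
  obs <- as.matrix(obs)
  S <- nrow(obs); J <- ncol(obs)
  if (is.null(rownames(obs))) rownames(obs) <- sprintf("site_%03d", seq_len(S))
  if (!any(obs == 2, na.rm = TRUE) && is.null(fix$R) && is.null(fix$delta)) {
    warning("no code-2 observation: R and delta are weakly identified.")
  }
  if (!is.null(X)) {
    X <- tibble::as_tibble(X)[match(rownames(obs), X$site_id), , drop = FALSE]
  }
  Xpsi <- ms_design(X, psi_terms, S)
  XR <- ms_design(X, R_terms, S)
  if (!is.null(W)) {
    W <- dplyr::arrange(tibble::as_tibble(W), .data$survey, .data$site_id)
    if (nrow(W) != S * J) stop("`W` must have one row per site x survey.", call. = FALSE)
  }
  Wp <- ms_design(W, p_terms, S * J)
  Wd <- ms_design(W, delta_terms, S * J)

  blocks <- list()
  if (is.null(fix$psi)) blocks$psi <- colnames(Xpsi)
  if (is.null(fix$R)) blocks$R <- colnames(XR)
  if (p_shared) {
    if (is.null(fix$p1) && is.null(fix$p2)) blocks$p <- colnames(Wp)
  } else {
    if (is.null(fix$p1)) blocks$p1 <- colnames(Wp)
    if (is.null(fix$p2)) blocks$p2 <- colnames(Wp)
  }
  if (is.null(fix$delta)) blocks$delta <- colnames(Wd)
  sizes <- lengths(blocks)
  npar <- sum(sizes)
  idx <- split(seq_len(npar), rep(names(blocks), sizes))

  codes <- obs
  omiss <- is.na(codes)
  allzero <- apply(codes == 0 | omiss, 1, all)
  clamp <- function(p) pmin(1 - 1e-12, pmax(1e-12, p))

  unpack <- function(th) {
    g <- function(nm, Xm, fixval) {
      if (!is.null(fixval)) return(rep(fixval, nrow(Xm)))
      clamp(stats::plogis(drop(Xm %*% th[idx[[nm]]])))
    }
    psi <- g("psi", Xpsi, fix$psi)
    R <- g("R", XR, fix$R)
    if (p_shared) {
      pshared <- if (!is.null(fix$p1)) rep(fix$p1, S * J) else g("p", Wp, NULL)
      p1 <- p2 <- pshared
    } else {
      p1 <- g("p1", Wp, fix$p1)
      p2 <- g("p2", Wp, fix$p2)
    }
    delta <- g("delta", Wd, fix$delta)
    list(psi = psi, R = R,
         p1 = matrix(p1, S, J), p2 = matrix(p2, S, J),
         delta = matrix(delta, S, J))
  }

  nll <- function(th) {
    pr <- unpack(th)
    f1 <- matrix(1, S, J); f2 <- matrix(1, S, J)
    z0 <- !omiss & codes == 0
    z1 <- !omiss & codes == 1
    z2 <- !omiss & codes == 2
    f1[z0] <- 1 - pr$p1[z0]; f1[z1] <- pr$p1[z1]; f1[z2] <- 0
    f2[z0] <- 1 - pr$p2[z0]
    f2[z1] <- (pr$p2 * (1 - pr$delta))[z1]
    f2[z2] <- (pr$p2 * pr$delta)[z2]
    prod1 <- apply(f1, 1, prod); prod2 <- apply(f2, 1, prod)
    lik <- (1 - pr$psi) * allzero + pr$psi * (1 - pr$R) * prod1 +
      pr$psi * pr$R * prod2
    if (any(lik <= 0) || any(!is.finite(lik))) return(1e10)
    -sum(log(lik))
  }

  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 7L))
  starts <- c(list(rep(0, npar)),
              purrr::map(seq_len(max(0, n_starts - 1)),
                         ~ stats::rnorm(npar, 0, 1)))
  fits <- purrr::map(starts, function(st) {
    tryCatch(stats::optim(st, nll, method = "BFGS",
                          control = list(maxit = 500)),
             error = function(e) list(value = Inf))
  })
  restore_seed(old)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (!is.finite(best$value)) stop("multistate likelihood optimization failed.", call. = FALSE)
  th <- best$par
  H <- tryCatch(stats::optimHess(th, nll), error = function(e) NULL)
  vcov <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se <- if (!is.null(vcov)) sqrt(pmax(0, diag(vcov))) else rep(NA_real_, npar)
  boundary <- abs(th) > 8
  se[boundary] <- NA_real_

  est <- tibble::tibble(
    block = rep(names(blocks), sizes),
    term = unlist(blocks, use.names = FALSE),
    estimate = th, se = se, boundary = boundary
  )
  pr_hat <- unpack(th)
  probs <- tibble::tibble(
    parameter = c("psi", "R", "p1", "p2", "delta", "p2_x_delta"),
    mean_estimate = c(mean(pr_hat$psi), mean(pr_hat$R), mean(pr_hat$p1),
                      mean(pr_hat$p2), mean(pr_hat$delta),
                      mean(pr_hat$p2 * pr_hat$delta))
  )
  structure(list(estimates = est, vcov = vcov, logLik = -best$value,
                 probabilities = probs, blocks = blocks, idx = idx, fix = fix,
                 p_shared = p_shared, convergence = best$convergence %||% NA,
                 nll_fn = nll,
                 design = list(Xpsi = Xpsi, XR = XR, Wp = Wp, Wd = Wd),
                 site_ids = rownames(obs)),
            class = "multistate_fit")
}

#' @export
print.multistate_fit <- function(x, ...) {
  cat(sprintf("<multistate_fit> logLik %.3f\n", x$logLik))
  print(x$estimates)
  print(x$probabilities)
  invisible(x)
}

#' Link-scale parameter table of a multistate fit
#' @param x a `multistate_fit`.
#' @param ... unused.
#' @return tibble of block, term, estimate, se, boundary.
#' @exportS3Method generics::tidy
tidy.multistate_fit <- function(x, ...) x$estimates

#' One-row multistate fit summary
#' @param x a `multistate_fit`.
#' @param ... unused.
#' @return tibble with logLik, parameter count, convergence code, and the
#'   mean probability-scale estimates.
#' @exportS3Method generics::glance
glance.multistate_fit <- function(x, ...) {
  w <- stats::setNames(as.list(x$probabilities$mean_estimate),
                       x$probabilities$parameter)
  dplyr::bind_cols(
    tibble::tibble(logLik = x$logLik, n_par = nrow(x$estimates),
                   convergence = x$convergence),
    tibble::as_tibble(w)
  )
}

#' Per-site conditional cohort-occurrence probability
#'
#' Inverse-logit of the fitted `R` linear predictor at each site, with a
#' delta-method 95% band computed on the logit scale and transformed.
#'
#' @param model a `multistate_fit` with free `R`.
#' @param X site covariate tibble covering the fitted `R` terms (default:
#'   the fitted design).
#' @return tibble: `site_id`, `R_hat`, `lower`, `upper`.
#' @export
conditional_occurrence <- function(model, X = NULL) {
  stopifnot(inherits(model, "multistate_fit"))
  if (is.null(model$blocks$R)) stop("`R` was fixed in this fit.", call. = FALSE)
  XR <- if (is.null(X)) model$design$XR else build_design_matrix(
    tibble::as_tibble(X), model$blocks$R)
  thR <- model$estimates$estimate[model$idx$R]
  eta <- drop(XR %*% thR)
  if (!is.null(model$vcov)) {
    Vr <- model$vcov[model$idx$R, model$idx$R, drop = FALSE]
    sev <- sqrt(pmax(0, rowSums((XR %*% Vr) * XR)))
  } else {
    sev <- rep(NA_real_, length(eta))
  }
  ids <- if (is.null(X)) model$site_ids else
    (X$site_id %||% sprintf("site_%03d", seq_len(nrow(XR))))
  tibble::tibble(site_id = ids,
                 R_hat = stats::plogis(eta),
                 lower = stats::plogis(eta - 1.96 * sev),
                 upper = stats::plogis(eta + 1.96 * sev))
}

#' Simulate detection histories from the three-state occupancy model
#'
#' Draws each site's latent state (unoccupied / occupied without cohort /
#' occupied with cohort) and then per-survey 0/1/2 codes under the
#' conditional binomial observation model, for direct parameter-recovery
#' studies.
#'
#' @param n_sites,n_surveys design dimensions.
#' @param psi,R,p1,p2,delta generating probabilities (scalars).
#' @param seed integer RNG seed.
#' @return S x J integer matrix of codes with site-id rownames.
#' @export
simulate_multistate <- function(n_sites, n_surveys, psi = 0.7, R = 0.6,
                                p1 = 0.45, p2 = 0.45, delta = 0.4, seed = 1) {
  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 8L))
  state <- sample(0:2, n_sites, replace = TRUE,
                  prob = c(1 - psi, psi * (1 - R), psi * R))
  obs <- matrix(0L, n_sites, n_surveys,
                dimnames = list(sprintf("site_%03d", seq_len(n_sites)), NULL))
  for (i in seq_len(n_sites)) {
    if (state[i] == 1L) {
      obs[i, ] <- stats::rbinom(n_surveys, 1L, p1)
    } else if (state[i] == 2L) {
      det <- stats::rbinom(n_surveys, 1L, p2)
      obs[i, ] <- det * (1L + stats::rbinom(n_surveys, 1L, delta))
    }
  }
  restore_seed(old)
  obs
}
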