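#' Model specification for the binomial-mixture abundance model
#'
#' @param abundance_terms character vector of abundance (log-scale) terms;
#'   `"(Intercept)"` is added if absent. `"A:B"` and `"A^2"` follow the
#'   design-matrix conventions of [build_design_matrix()].
#' @param detection_terms detection (logit-scale) terms, same conventions.
#' @param family `"poisson"` or `"zip"` (zero-inflated Poisson).
#' @param detection_random_effect include a plot-survey normal random
#'   effect in the detection model.
#' @param prior_sd SD of the Normal(0, prior_sd^2) prior on every
#'   regression coefficient (default 1000, i.e. variance 10^6).
#' @param sigma_prior_sd scale of the half-Normal prior on the random-effect
#'   SD.
#' @param n_max truncation bound for the latent abundances; default
#'   `max(y) + 50`, chosen at fit time.
#' @param fix_detection_at optional numeric vector pinning the detection
#'   coefficients (logit scale, one per detection term); used when
#'   detection is known, e.g. in diagnostic toys.
#' @return an `nmix_spec` list.
#' @export
nmix_spec <- function(abundance_terms = "(Intercept)",
                      detection_terms = "(Intercept)",
                      family = c("poisson", "zip"),
                      detection_random_effect = FALSE,
                      prior_sd = 1000, sigma_prior_sd = 10, n_max = NULL,
                      fix_detection_at = NULL) {
  family <- match.arg(family)
  if (prior_sd <= 0) stop("`prior_sd` must be positive.", call. = FALSE)
  add_int <- function(t) if ("(Intercept)" %in% t) t else c("(Intercept)", t)
  detection_terms <- add_int(detection_terms)
  if (!is.null(fix_detection_at) &&
      length(fix_detection_at) != length(detection_terms)) {
    stop("`fix_detection_at` must give one value per detection term.", call. = FALSE)
  }
  structure(list(abundance_terms = add_int(abundance_terms),
                 detection_terms = detection_terms,
                 family = family,
                 detection_random_effect = detection_random_effect,
                 prior_sd = prior_sd, sigma_prior_sd = sigma_prior_sd,
                 n_max = n_max, fix_detection_at = fix_detection_at),
            class = "nmix_spec")
}

#' MCMC settings
#'
#' Desk-scale defaults (3 chains of 20,000 iterations, 10,000 burn-in,
#' thinning 10). The field study's long run (500,000 / 250,000 / 50) is
#' available by argument.
#'
#' @param chains number of chains (>= 2 for Rhat).
#' @param iterations total iterations per chain (> burn_in).
#' @param burn_in discarded initial iterations.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; chains use derived child seeds.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 3, iterations = 20000, burn_in = 10000,
                        thin = 10, seed = 1) {
  if (iterations <= burn_in) stop("`iterations` must exceed `burn_in`.", call. = FALSE)
  if (thin < 1) stop("`thin` must be >= 1.", call. = FALSE)
  structure(list(chains = as.integer(chains), iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Marginal log-likelihood of one site's count history
#'
#' The latent abundance is summed out:
#' `L_i = phi * [all y = 0] + (1 - phi) * sum_N Pois(N; lambda) *
#' prod_j Binom(y_ij; N, p_ij)`, truncated at `n_max`. Missing surveys
#' (NA) are dropped from the product.
#'
#' @param y_i integer count vector over surveys (NA allowed).
#' @param lambda_i expected abundance (> 0).
#' @param p_i detection probability per survey (recycled if length 1).
#' @param n_max truncation bound (>= max(y_i)).
#' @param phi zero-inflation probability.
#' @return the log-likelihood (may be `-Inf`).
#' @export
marginal_site_loglik <- function(y_i, lambda_i, p_i, n_max = 200, phi = 0) {
  if (any(!is.na(y_i) & y_i < 0)) stop("counts must be nonnegative.", call. = FALSE)
  keep <- !is.na(y_i)
  y <- y_i[keep]
  p <- rep_len(p_i, length(y_i))[keep]
  if (any(p < 0 | p > 1)) stop("`p_i` must lie in [0, 1].", call. = FALSE)
  maxy <- if (length(y)) max(y) else 0L
  if (n_max < maxy) stop("`n_max` must be >= max(y_i).", call. = FALSE)
  Ns <- maxy:n_max
  lp <- stats::dpois(Ns, lambda_i, log = TRUE)
  for (j in seq_along(y)) {
    lp <- lp + stats::dbinom(y[j], Ns, p[j], log = TRUE)
  }
  m <- max(lp)
  lsum <- if (is.finite(m)) m + log(sum(exp(lp - m))) else -Inf
  if (phi > 0) {
    allzero <- length(y) == 0 || all(y == 0)
    lz <- if (allzero) log(phi) else -Inf
    ls1 <- log1p(-phi) + lsum
    m2 <- max(lz, ls1)
    if (!is.finite(m2)) return(-Inf)
    return(m2 + log(sum(exp(c(lz, ls1) - m2))))
  }
  lsum
}

#' Gelman-Rubin potential scale reduction
#'
#' `Rhat = sqrt(Vhat / W)` with `W` the mean within-chain variance,
#' `B = n * var(chain means)` and `Vhat = ((n - 1)/n) W + B/n`.
#'
#' @param chains list of equal-length numeric draw vectors (>= 2 chains).
#' @return the Rhat statistic.
#' @export
gelman_rubin <- function(chains) {
  if (length(chains) < 2) stop("need at least 2 chains.", call. = FALSE)
  n <- unique(vapply(chains, length, integer(1)))
  if (length(n) != 1) stop("chains must have equal length.", call. = FALSE)
  if (n < 2) stop("chains must have length >= 2.", call. = FALSE)
  W <- mean(vapply(chains, stats::var, numeric(1)))
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  if (W == 0) return(1)
  Vhat <- (n - 1) / n * W + B / n
  sqrt(Vhat / W)
}

dataset_matrices <- function(data, spec) {
  y <- data$y
  S <- nrow(y); J <- ncol(y)
  if (is.null(data$X)) {
    X <- tibble::tibble(site_id = rownames(y))
  } else {
    X <- tibble::as_tibble(data$X)
    X <- X[match(rownames(y), X$site_id), , drop = FALSE]
  }
  Xab <- build_design_matrix(X, spec$abundance_terms)
  if (is.null(data$W)) {
    W <- tidyr::expand_grid(survey = seq_len(J), site_id = rownames(y))
  } else {
    W <- dplyr::arrange(tibble::as_tibble(data$W), .data$survey, .data$site_id)
    if (nrow(W) != S * J) stop("`W` must have one row per site x survey.", call. = FALSE)
    if (!identical(W$site_id, rep(rownames(y), times = J))) {
      W <- W[order(W$survey, match(W$site_id, rownames(y))), ]
    }
  }
  Wdet <- build_design_matrix(W, spec$detection_terms)
  list(Xab = Xab, Wdet = Wdet)
}

#' Fit the binomial-mixture model by MCMC
#'
#' Data-augmented Metropolis-within-Gibbs sampling (see the package
#' vignette for the update scheme) under Normal(0, `prior_sd`^2) priors on
#' all regression coefficients and a half-Normal prior on the
#' random-effect SD. Runs `mcmc$chains` chains from over-dispersed RNG
#' streams and reports per-parameter posterior summaries, Rhat, and a
#' posterior predictive check (Bayesian p-value and chi-square discrepancy
#' ratio).
#'
#' @param data a [survey_dataset()].
#' @param spec an [nmix_spec()].
#' @param mcmc an [mcmc_config()].
#' @return an `nmix_fit`: draws, `summary` tibble, `site_abundance`
#'   tibble, `bayes_p`, `chisq_ratio`, `converged` flag.
#' @export
nmix_fit <- function(data, spec = nmix_spec(), mcmc = mcmc_config()) {
  stopifnot(inherits(data, "survey_dataset"))
  mats <- dataset_matrices(data, spec)
  y <- data$y
  ymiss <- y
  ymiss[is.na(ymiss)] <- -1L
  storage.mode(ymiss) <- "integer"
  n_max <- spec$n_max %||% (max(y, na.rm = TRUE) + 50L)
  if (n_max <= max(y, na.rm = TRUE)) {
    stop("`n_max` must exceed the maximum observed count.", call. = FALSE)
  }
  fam <- if (spec$family == "zip") 1L else 0L
  old <- .Random.seed_exists()
  chains <- vector("list", mcmc$chains)
  hit <- FALSE
  for (ch in seq_len(mcmc$chains)) {
    set.seed(child_seed(mcmc$seed, 100L + ch))
    res <- .nmix_mcmc_chain_cpp(ymiss, mats$Xab, mats$Wdet, fam,
                                spec$detection_random_effect,
                                mcmc$iterations, mcmc$burn_in, mcmc$thin,
                                spec$prior_sd, spec$sigma_prior_sd,
                                as.integer(n_max),
                                as.numeric(spec$fix_detection_at %||% numeric(0)))
    hit <- hit || res$hit_nmax
    chains[[ch]] <- res
  }
  restore_seed(old)
  if (hit) warning("latent abundance reached `n_max`; consider raising it.")

  # mean detection = detection at average (zero) covariates, i.e. the
  # inverse-logit of the detection intercept draw by draw
  pnames <- c(paste0("beta[", spec$abundance_terms, "]"),
              paste0("alpha[", spec$detection_terms, "]"),
              if (spec$detection_random_effect) "sigma_p",
              if (fam == 1L) "phi",
              "mean_detection", "realized_detection")
  chain_mat <- function(res) {
    cbind(res$beta, res$alpha,
          if (spec$detection_random_effect) res$sigma,
          if (fam == 1L) res$phi,
          stats::plogis(res$alpha[, 1]),
          res$mean_p)
  }
  mats_by_chain <- lapply(chains, chain_mat)
  draws <- do.call(rbind, mats_by_chain)
  colnames(draws) <- pnames

  summary_tbl <- purrr::map_dfr(seq_along(pnames), function(k) {
    v <- draws[, k]
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    rhat <- if (length(mats_by_chain) >= 2) {
      gelman_rubin(lapply(mats_by_chain, function(m) m[, k]))
    } else NA_real_
    tibble::tibble(parameter = pnames[k], mean = mean(v), sd = stats::sd(v),
                   lower = q[1], upper = q[2], rhat = rhat)
  })

  Ndraws <- do.call(rbind, lapply(chains, `[[`, "N"))
  site_abundance <- tibble::tibble(
    site_id = rownames(y),
    mean = colMeans(Ndraws),
    lower = apply(Ndraws, 2, stats::quantile, 0.025),
    upper = apply(Ndraws, 2, stats::quantile, 0.975)
  )
  Tobs <- unlist(lapply(chains, `[[`, "T_obs"))
  Trep <- unlist(lapply(chains, `[[`, "T_rep"))
  bayes_p <- mean(Trep >= Tobs)
  chisq_ratio <- mean(Tobs) / mean(Trep)
  core <- !summary_tbl$parameter %in% c("mean_detection", "realized_detection")
  converged <- all(summary_tbl$rhat[core] <= 1.1, na.rm = TRUE)

  structure(list(draws = draws, chains = mats_by_chain, N_draws = Ndraws,
                 summary = summary_tbl, site_abundance = site_abundance,
                 bayes_p = bayes_p, chisq_ratio = chisq_ratio,
                 converged = converged, spec = spec, mcmc = mcmc,
                 n_max = n_max, data_dim = dim(y)),
            class = "nmix_fit")
}

#' @export
print.nmix_fit <- function(x, ...) {
  cat(sprintf("<nmix_fit> %s%s, %d x %d counts, %d draws\n",
              x$spec$family,
              if (x$spec$detection_random_effect) " + detection RE" else "",
              x$data_dim[1], x$data_dim[2], nrow(x$draws)))
  cat(sprintf("  Bayesian p-value %.3f, chi-square ratio %.3f, %s\n",
              x$bayes_p, x$chisq_ratio,
              if (x$converged) "converged (all Rhat <= 1.1)" else "NOT converged"))
  print(x$summary, n = 20)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a binomial-mixture fit
#'
#' @param x an `nmix_fit`.
#' @param ... unused.
#' @return tibble: parameter, mean, sd, lower, upper (95% CRI), rhat.
#' @exportS3Method generics::tidy
tidy.nmix_fit <- function(x, ...) x$summary

#' One-row model-level summary of a binomial-mixture fit
#'
#' @param x an `nmix_fit`.
#' @param ... unused.
#' @return tibble with fit diagnostics.
#' @exportS3Method generics::glance
glance.nmix_fit <- function(x, ...) {
  tibble::tibble(
    family = x$spec$family,
    detection_random_effect = x$spec$detection_random_effect,
    n_sites = x$data_dim[1], n_surveys = x$data_dim[2],
    n_draws = nrow(x$draws),
    bayes_p = x$bayes_p, chisq_ratio = x$chisq_ratio,
    max_rhat = max(x$summary$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

#' Coefficient interval plot for a binomial-mixture fit
#'
#' @param object an `nmix_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.nmix_fit <- function(object, ...) {
  d <- dplyr::filter(object$summary,
                     !.data$parameter %in% c("mean_detection", "realized_detection"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$parameter)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower, xmax = .data$upper)) +
    ggplot2::labs(x = "posterior mean (95% CRI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Posterior predictive check summaries
#'
#' @param fit an `nmix_fit`.
#' @return tibble with `bayes_p` and `chisq_ratio`.
#' @export
posterior_predictive_check <- function(fit) {
  stopifnot(inherits(fit, "nmix_fit"))
  tibble::tibble(bayes_p = fit$bayes_p, chisq_ratio = fit$chisq_ratio)
}

#' Project expected abundance across the landscape
#'
#' Per pixel, the posterior mean of `lambda = exp(x' beta)` (times
#' `1 - phi` under zero inflation), averaging `exp()` over draws rather
#' than exponentiating the posterior mean. Covariate rasters are raw; the
#' centres/scales from the fitted data put them on the model scale, and
#' interaction/quadratic terms are formed from the scaled values.
#'
#' @param fit an `nmix_fit`.
#' @param covariate_rasters named list of `terra_raster`s covering the base
#'   abundance covariates, co-registered.
#' @param centers,scales named standardization constants (from
#'   [standardize_covariates()]).
#' @param quantiles optional CRI probabilities, e.g. `c(0.025, 0.975)`.
#' @return a `terra_raster` of expected abundance, with `lower`/`upper`
#'   rasters attached as attributes when `quantiles` is given.
#' @export
predict_abundance <- function(fit, covariate_rasters, centers = NULL,
                              scales = NULL, quantiles = NULL) {
  stopifnot(inherits(fit, "nmix_fit"))
  terms <- fit$spec$abundance_terms
  bt <- base_terms(terms)
  ref <- covariate_rasters[[bt[1]]]
  for (nm in bt) {
    if (is.null(covariate_rasters[[nm]])) {
      stop(sprintf("missing covariate raster `%s`.", nm), call. = FALSE)
    }
    if (!same_grid(covariate_rasters[[nm]], ref)) {
      stop("covariate rasters are not on a common grid.", call. = FALSE)
    }
  }
  npix <- length(ref$values)
  cols <- lapply(bt, function(nm) {
    v <- as.vector(covariate_rasters[[nm]]$values)
    if (!is.null(centers) && nm %in% names(centers)) {
      v <- (v - centers[[nm]]) / scales[[nm]]
    }
    v
  })
  dat <- stats::setNames(as.data.frame(cols), bt)
  P <- build_design_matrix(dat, terms)
  B <- fit$draws[, paste0("beta[", terms, "]"), drop = FALSE]
  zip <- fit$spec$family == "zip"
  occ <- if (zip) 1 - fit$draws[, "phi"] else rep(1, nrow(B))
  mu <- rep(NA_real_, npix)
  lo <- hi <- if (!is.null(quantiles)) rep(NA_real_, npix)
  chunk <- 20000L
  for (s in seq(1L, npix, by = chunk)) {
    idx <- s:min(npix, s + chunk - 1L)
    E <- exp(P[idx, , drop = FALSE] %*% t(B))
    E <- sweep(E, 2, occ, `*`)
    mu[idx] <- rowMeans(E)
    if (!is.null(quantiles)) {
      q <- t(apply(E, 1, stats::quantile, probs = quantiles, na.rm = TRUE))
      lo[idx] <- q[, 1]; hi[idx] <- q[, 2]
    }
  }
  out <- raster_like(ref, matrix(mu, nrow(ref$values), ncol(ref$values)))
  if (!is.null(quantiles)) {
    attr(out, "lower") <- raster_like(ref, matrix(lo, nrow(ref$values), ncol(ref$values)))
    attr(out, "upper") <- raster_like(ref, matrix(hi, nrow(ref$values), ncol(ref$values)))
  }
  out
}
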