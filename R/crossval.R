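#' Leave-one-out cross-validation of site abundance
#'
#' For each held-out site the counts are masked (covariates untouched),
#' the model is refit, and the site's posterior *predictive* abundance is
#' drawn from its covariates: a lambda draw per posterior sample, then a
#' Poisson draw for N (`predict = "lambda"` skips the Poisson stage). The
#' full-model posterior mean abundance at that site is compared with the
#' LOO 95% CRI; lying outside it counts as an exceedance. The error-rate
#' denominator follows the reference arithmetic of excluding one site
#' (`denominator = "n_minus_one"`, e.g. 134 of 135); `"all"` uses every
#' compared site.
#'
#' @param data a [survey_dataset()].
#' @param spec an [nmix_spec()] (the final model).
#' @param mcmc an [mcmc_config()] for the refits (reduced length is the
#'   intended default).
#' @param sites optional character subset of site ids to hold out.
#' @param full_fit optional precomputed full-data `nmix_fit`.
#' @param predict `"N"` (predictive abundance draw) or `"lambda"`.
#' @param denominator `"n_minus_one"` or `"all"`.
#' @return an `loo_result`: `sites` tibble (site, full estimate, LOO mean
#'   and CRI, exceedance flag) and one-row `summary` tibble (mean
#'   |difference|, SD of differences, error rate %).
#' @export
loo_cross_validate <- function(data, spec, mcmc = mcmc_config(chains = 2),
                               sites = NULL, full_fit = NULL,
                               predict = c("N", "lambda"),
                               denominator = c("n_minus_one", "all")) {
  predict <- match.arg(predict)
  denominator <- match.arg(denominator)
  stopifnot(inherits(data, "survey_dataset"))
  all_sites <- rownames(data$y)
  if (is.null(sites)) sites <- all_sites
  if (length(sites) < 1) stop("`sites` must name at least one site.", call. = FALSE)
  if (length(all_sites) < 3) stop("need at least 3 sites.", call. = FALSE)
  if (is.null(full_fit)) {
    full_fit <- nmix_fit(data, spec, mcmc)
  }
  full_est <- full_fit$site_abundance
  terms <- spec$abundance_terms
  zip <- spec$family == "zip"
  old <- .Random.seed_exists()
  rows <- purrr::map_dfr(seq_along(sites), function(k) {
    s <- sites[k]
    d2 <- data
    d2$y[s, ] <- NA_integer_
    mc <- mcmc_config(mcmc$chains, mcmc$iterations, mcmc$burn_in, mcmc$thin,
                      child_seed(mcmc$seed, 300L + k))
    f2 <- nmix_fit(d2, spec, mc)
    X1 <- tibble::as_tibble(data$X)[match(s, data$X$site_id), , drop = FALSE]
    xrow <- build_design_matrix(X1, terms)
    B <- f2$draws[, paste0("beta[", terms, "]"), drop = FALSE]
    lam <- exp(drop(B %*% t(xrow)))
    set.seed(child_seed(mcmc$seed, 600L + k))
    if (zip) {
      lam <- lam * (stats::runif(length(lam)) >= f2$draws[, "phi"])
    }
    pred <- if (predict == "N") stats::rpois(length(lam), lam) else lam
    q <- stats::quantile(pred, c(0.025, 0.975), names = FALSE)
    full_m <- full_est$mean[match(s, full_est$site_id)]
    tibble::tibble(site_id = s, full_estimate = full_m,
                   loo_mean = mean(pred), loo_lower = q[1], loo_upper = q[2],
                   exceeded = full_m < q[1] | full_m > q[2])
  })
  restore_seed(old)
  diffs <- rows$loo_mean - rows$full_estimate
  denom <- if (denominator == "n_minus_one") max(1L, nrow(rows) - 1L) else nrow(rows)
  summary_tbl <- tibble::tibble(
    n_heldout = nrow(rows),
    mean_abs_difference = mean(abs(diffs)),
    sd_difference = stats::sd(diffs),
    n_exceedances = sum(rows$exceeded),
    error_rate_pct = 100 * sum(rows$exceeded) / denom
  )
  structure(list(sites = rows, summary = summary_tbl, full_fit = full_fit,
                 denominator = denominator),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("<loo_result> %d held-out sites\n", nrow(x$sites)))
  print(x$summary)
  invisible(x)
}

#' Per-site LOO comparisons
#' @param x an `loo_result`.
#' @param ... unused.
#' @return the per-site tibble.
#' @exportS3Method generics::tidy
tidy.loo_result <- function(x, ...) x$sites

#' One-row LOO summary
#' @param x an `loo_result`.
#' @param ... unused.
#' @return the summary tibble.
#' @exportS3Method generics::glance
glance.loo_result <- function(x, ...) x$summary

#' Full-model vs LOO abundance plot
#' @param object an `loo_result`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.loo_result <- function(object, ...) {
  d <- object$sites
  ggplot2::ggplot(d, ggplot2::aes(x = .data$full_estimate, y = .data$loo_mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$loo_lower,
                                          ymax = .data$loo_upper,
                                          colour = .data$exceeded)) +
    ggplot2::labs(x = "full-model abundance estimate",
                  y = "LOO posterior predictive abundance") +
    ggplot2::theme_minimal()
}
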