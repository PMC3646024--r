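#' Choose the abundance-model parameterization
#'
#' Fits the plain Poisson, zero-inflated Poisson, and detection-random-
#' effect parameterizations with the full covariate sets and ranks them by
#' posterior predictive fit, |Bayesian p-value - 0.5| (closest to 0.5
#' wins), gated on convergence (all Rhat <= 1.1). Non-converged models
#' rank after converged ones; if none converges the step fails with the
#' full diagnostic table attached.
#'
#' @param data a [survey_dataset()].
#' @param abundance_terms,detection_terms full candidate term sets.
#' @param mcmc an [mcmc_config()].
#' @param prior_sd coefficient prior SD.
#' @return list: `family`, `detection_random_effect`, `diagnostics`
#'   (one row per candidate), `fits` (named list of `nmix_fit`s).
#' @export
choose_parameterization <- function(data, abundance_terms, detection_terms,
                                    mcmc = mcmc_config(), prior_sd = 1000) {
  cands <- list(
    poisson = list(family = "poisson", re = FALSE),
    zip = list(family = "zip", re = FALSE),
    random_effect = list(family = "poisson", re = TRUE)
  )
  fits <- purrr::imap(cands, function(cd, nm) {
    spec <- nmix_spec(abundance_terms, detection_terms, family = cd$family,
                      detection_random_effect = cd$re, prior_sd = prior_sd)
    nmix_fit(data, spec, mcmc)
  })
  diagnostics <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(parameterization = nm,
                   bayes_p = f$bayes_p, chisq_ratio = f$chisq_ratio,
                   fit_distance = abs(f$bayes_p - 0.5),
                   max_rhat = max(f$summary$rhat, na.rm = TRUE),
                   converged = f$converged)
  })
  ord <- order(!diagnostics$converged, diagnostics$fit_distance)
  diagnostics <- diagnostics[ord, ]
  if (!any(diagnostics$converged)) {
    stop(paste0("no parameterization converged (all Rhat > 1.1):\n",
                paste(utils::capture.output(print(diagnostics)), collapse = "\n")),
         call. = FALSE)
  }
  best <- diagnostics$parameterization[1]
  list(family = cands[[best]]$family,
       detection_random_effect = cands[[best]]$re,
       chosen = best, diagnostics = diagnostics, fits = fits)
}

retained_terms <- function(summary_tbl, prefix, candidates) {
  rows <- summary_tbl[summary_tbl$parameter %in% paste0(prefix, "[", candidates, "]"), ]
  terms <- sub(paste0("^", prefix, "\\["), "", sub("\\]$", "", rows$parameter))
  keep <- terms[!(rows$lower <= 0 & rows$upper >= 0)]
  keep <- setdiff(keep, "(Intercept)")
  # hierarchy: a retained quadratic or interaction keeps its linear parents
  parents <- base_terms(keep)
  union(keep, intersect(parents, candidates))
}

step_rows <- function(fit, step, model) {
  s <- fit$summary
  s <- s[grepl("^(beta|alpha)\\[", s$parameter), ]
  tibble::tibble(step = step, model = model, parameter = s$parameter,
                 mean = s$mean, lower = s$lower, upper = s$upper,
                 rhat = s$rhat)
}

#' Credible-interval covariate selection
#'
#' The staged model-construction procedure: (a) all detection covariates
#' with constant abundance, retaining those whose 95% CRI excludes zero;
#' (b) a confirmation refit of the retained detection set, checking that
#' signs are stable; (c) with that detection model, all abundance
#' covariates, retained by the same rule; (d) the final joint model. A
#' retained quadratic (`"A^2"`) or interaction (`"A:B"`) always keeps its
#' linear parent terms. If nothing is retained the model falls back to
#' intercept-only with a notice in the trace.
#'
#' @param data a [survey_dataset()].
#' @param family,detection_random_effect parameterization (from
#'   [choose_parameterization()]).
#' @param abundance_terms,detection_terms candidate term sets (no
#'   intercept needed).
#' @param mcmc an [mcmc_config()]; step seeds are derived from it.
#' @param prior_sd coefficient prior SD.
#' @return a `selection_trace`: `steps` tibble (one row per parameter per
#'   step with retention decisions implicit in the next step's model),
#'   `retained_detection`, `retained_abundance`, `final_spec`,
#'   `final_fit`, `notes`.
#' @export
select_covariates <- function(data, family = "poisson",
                              detection_random_effect = FALSE,
                              abundance_terms, detection_terms,
                              mcmc = mcmc_config(), prior_sd = 1000) {
  notes <- character(0)
  mc_step <- function(k) mcmc_config(mcmc$chains, mcmc$iterations, mcmc$burn_in,
                                     mcmc$thin, child_seed(mcmc$seed, 200L + k))
  # (a) detection screening, constant abundance
  spec2 <- nmix_spec("(Intercept)", detection_terms, family = family,
                     detection_random_effect = detection_random_effect,
                     prior_sd = prior_sd)
  fit2 <- nmix_fit(data, spec2, mc_step(1L))
  det_keep <- retained_terms(fit2$summary, "alpha", spec2$detection_terms)
  steps <- step_rows(fit2, 1L, "detection screening")
  if (length(det_keep) == 0) {
    notes <- c(notes, "no detection covariate retained; detection is intercept-only")
  }
  # (b) confirmation refit
  spec3 <- nmix_spec("(Intercept)", det_keep, family = family,
                     detection_random_effect = detection_random_effect,
                     prior_sd = prior_sd)
  fit3 <- nmix_fit(data, spec3, mc_step(2L))
  steps <- dplyr::bind_rows(steps, step_rows(fit3, 2L, "detection confirmation"))
  common <- intersect(fit2$summary$parameter, fit3$summary$parameter)
  common <- setdiff(common[grepl("^alpha", common)], "alpha[(Intercept)]")
  s2 <- fit2$summary$mean[match(common, fit2$summary$parameter)]
  s3 <- fit3$summary$mean[match(common, fit3$summary$parameter)]
  if (length(common) && any(sign(s2) != sign(s3))) {
    notes <- c(notes, sprintf("sign flipped between screening and confirmation: %s",
                              paste(common[sign(s2) != sign(s3)], collapse = ", ")))
  }
  # (c) abundance screening with the confirmed detection model
  spec4 <- nmix_spec(abundance_terms, det_keep, family = family,
                     detection_random_effect = detection_random_effect,
                     prior_sd = prior_sd)
  fit4 <- nmix_fit(data, spec4, mc_step(3L))
  ab_keep <- retained_terms(fit4$summary, "beta", spec4$abundance_terms)
  steps <- dplyr::bind_rows(steps, step_rows(fit4, 3L, "abundance screening"))
  if (length(ab_keep) == 0) {
    notes <- c(notes, "no abundance covariate retained; abundance is intercept-only")
  }
  # (d) final joint model
  spec5 <- nmix_spec(ab_keep, det_keep, family = family,
                     detection_random_effect = detection_random_effect,
                     prior_sd = prior_sd)
  fit5 <- nmix_fit(data, spec5, mc_step(4L))
  steps <- dplyr::bind_rows(steps, step_rows(fit5, 4L, "final joint model"))
  structure(list(steps = steps,
                 retained_detection = det_keep,
                 retained_abundance = ab_keep,
                 final_spec = spec5, final_fit = fit5, notes = notes),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace>\n")
  cat("  retained detection:", paste(x$retained_detection, collapse = ", "), "\n")
  cat("  retained abundance:", paste(x$retained_abundance, collapse = ", "), "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy the final model of a selection trace
#' @param x a `selection_trace`.
#' @param ... unused.
#' @return the final fit's summary tibble.
#' @exportS3Method generics::tidy
tidy.selection_trace <- function(x, ...) tidy(x$final_fit)
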