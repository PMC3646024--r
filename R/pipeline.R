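#' Read a repeated-count survey CSV
#'
#' Wide format: `site_id`, then one integer column per survey
#' (`survey_1` ... `survey_J`); empty cells are missed surveys.
#'
#' @param path CSV path.
#' @return a [survey_dataset()] (without covariates).
#' @export
read_survey_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"site_id" %in% names(d)) stop("survey CSV needs a `site_id` column.", call. = FALSE)
  dup <- d$site_id[duplicated(d$site_id)]
  if (length(dup)) {
    stop(sprintf("duplicate site_id: %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  cols <- setdiff(names(d), "site_id")
  y <- as.matrix(d[cols])
  storage.mode(y) <- "integer"
  neg <- which(!is.na(y) & y < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative count at row %d (site %s), column `%s`.",
                 neg[1, 1] + 1L, d$site_id[neg[1, 1]], cols[neg[1, 2]]),
         call. = FALSE)
  }
  rownames(y) <- d$site_id
  survey_dataset(y)
}

#' Write a survey dataset's counts as CSV
#'
#' Canonical wide form: `site_id`, `survey_1..J`. `write(read(x))` is
#' byte-identical on this form.
#'
#' @param data a [survey_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(data, path) {
  y <- data$y
  d <- data.frame(site_id = rownames(y), y, check.names = FALSE)
  names(d) <- c("site_id", sprintf("survey_%d", seq_len(ncol(y))))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

write_long_covariates <- function(W, path) {
  long <- tidyr::pivot_longer(W, -c("site_id", "survey"),
                              names_to = "covariate", values_to = "value")
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_long_covariates <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  tidyr::pivot_wider(d, names_from = "covariate", values_from = "value")
}

#' Assemble and validate a pipeline configuration
#'
#' @param input `"synthetic"` or a list of paths (`counts`,
#'   `site_covariates`, `survey_covariates`, optional `dem`).
#' @param out_dir artifact directory (created if needed).
#' @param seed global integer seed.
#' @param design a [study_design()] (synthetic input).
#' @param truth a [truth_params()] (synthetic input).
#' @param landscape derive covariates from a generated DEM (synthetic).
#' @param extent_cells,cell_m landscape dimensions (synthetic).
#' @param choose_family run the parameterization-choice stage, or a fixed
#'   `list(family =, detection_random_effect =)`.
#' @param select run CRI covariate selection (else fit the full model).
#' @param abundance_terms,detection_terms candidate terms.
#' @param mcmc an [mcmc_config()].
#' @param loo run leave-one-out cross-validation (`FALSE`, `TRUE`, or a
#'   site count to subsample).
#' @param multistate fit the cohort multistate models.
#' @param predict_map write the landscape abundance projection.
#' @return validated `pipeline_config`.
#' @export
pipeline_config <- function(input = "synthetic", out_dir = tempfile("nmixterra_"),
                            seed = 1, design = study_design(),
                            truth = truth_params(), landscape = FALSE,
                            extent_cells = c(128, 128), cell_m = 12,
                            choose_family = FALSE, select = TRUE,
                            abundance_terms = setdiff(names(truth_params()$beta), "(Intercept)"),
                            detection_terms = setdiff(names(truth_params()$alpha), "(Intercept)"),
                            mcmc = mcmc_config(seed = seed),
                            loo = FALSE, multistate = TRUE,
                            predict_map = landscape) {
  if (!identical(input, "synthetic")) {
    if (!is.list(input) || is.null(input$counts)) {
      stop("`input` must be \"synthetic\" or a list with a `counts` path.", call. = FALSE)
    }
    for (f in unlist(input)) {
      if (!file.exists(f)) stop(sprintf("input file not found: %s", f), call. = FALSE)
    }
    if (predict_map && is.null(input$dem)) {
      stop("`predict_map` requires a DEM input.", call. = FALSE)
    }
  }
  structure(list(input = input, out_dir = out_dir, seed = as.integer(seed),
                 design = design, truth = truth, landscape = landscape,
                 extent_cells = extent_cells, cell_m = cell_m,
                 choose_family = choose_family, select = select,
                 abundance_terms = abundance_terms,
                 detection_terms = detection_terms,
                 mcmc = mcmc, loo = loo, multistate = multistate,
                 predict_map = predict_map),
            class = "pipeline_config")
}

stage_msg <- function(stage, seed) {
  message(sprintf("[nmixterra] stage %-22s seed %d", stage, seed))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: data (synthetic generation or CSV load) -> terrain
#' covariates (optional) -> parameterization choice (optional) -> CRI
#' covariate selection (optional) -> final fit with posterior predictive
#' check -> LOO cross-validation (optional) -> landscape abundance
#' projection (optional) -> cohort multistate models (optional) ->
#' summary regressions. Every stage logs its seed; artifacts (CSV tables,
#' ASCII grids, a JSON manifest with per-file hashes) are written under
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the fitted objects and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  res <- list(out_dir = out)

  stage_msg("data", seed)
  if (identical(config$input, "synthetic")) {
    sim <- simulate_study(config$design, config$truth, seed = seed,
                          landscape = config$landscape,
                          extent_cells = config$extent_cells,
                          cell_m = config$cell_m)
    data <- sim$data
    res$sim <- sim
    write_survey_csv(data, file.path(out, "counts.csv"))
    utils::write.csv(data$X, file.path(out, "site_covariates.csv"),
                     row.names = FALSE, quote = FALSE)
    write_long_covariates(data$W, file.path(out, "survey_covariates.csv"))
    for (nm in names(data$states)) {
      utils::write.csv(
        data.frame(site_id = rownames(data$states[[nm]]), data$states[[nm]]),
        file.path(out, sprintf("states_%s.csv", nm)), row.names = FALSE,
        quote = FALSE)
    }
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(config$truth[c("beta", "alpha", "sigma_p", "phi")],
                           file.path(out, "truth_params.json"), auto_unbox = TRUE,
                           digits = NA)
    }
    if (config$landscape) {
      write_ascii_grid(sim$dem, file.path(out, "dem.asc"))
    }
  } else {
    data <- read_survey_csv(config$input$counts)
    if (!is.null(config$input$site_covariates)) {
      data$X <- tibble::as_tibble(utils::read.csv(config$input$site_covariates,
                                                  stringsAsFactors = FALSE))
    }
    if (!is.null(config$input$survey_covariates)) {
      data$W <- read_long_covariates(config$input$survey_covariates)
    }
  }

  fam <- "poisson"; re <- TRUE
  if (isTRUE(config$choose_family)) {
    stage_msg("choose_parameterization", seed)
    ch <- choose_parameterization(data, config$abundance_terms,
                                  config$detection_terms, config$mcmc)
    fam <- ch$family; re <- ch$detection_random_effect
    res$parameterization <- ch$diagnostics
  } else if (is.list(config$choose_family)) {
    fam <- config$choose_family$family
    re <- config$choose_family$detection_random_effect
  }

  if (isTRUE(config$select)) {
    stage_msg("select_covariates", seed)
    tr <- select_covariates(data, fam, re, config$abundance_terms,
                            config$detection_terms, config$mcmc)
    res$selection <- tr
    utils::write.csv(tr$steps, file.path(out, "selection_steps.csv"),
                     row.names = FALSE, quote = FALSE)
    fit <- tr$final_fit
    spec <- tr$final_spec
  } else {
    stage_msg("fit", seed)
    spec <- nmix_spec(config$abundance_terms, config$detection_terms,
                      family = fam, detection_random_effect = re)
    fit <- nmix_fit(data, spec, config$mcmc)
  }
  res$fit <- fit
  tbl <- tidy(fit)
  utils::write.csv(
    data.frame(parameter = tbl$parameter, mean = tbl$mean,
               `2.5%` = tbl$lower, `97.5%` = tbl$upper, Rhat = tbl$rhat,
               check.names = FALSE),
    file.path(out, "posterior_summary.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(fit$site_abundance, file.path(out, "site_abundance.csv"),
                   row.names = FALSE, quote = FALSE)

  if (!isFALSE(config$loo)) {
    stage_msg("loo", seed)
    sub <- if (isTRUE(config$loo)) NULL else {
      utils::head(rownames(data$y), config$loo)
    }
    loo <- loo_cross_validate(data, spec,
                              mcmc_config(2, config$mcmc$iterations %/% 2,
                                          config$mcmc$burn_in %/% 2,
                                          config$mcmc$thin, seed),
                              sites = sub, full_fit = fit)
    res$loo <- loo
    utils::write.csv(loo$sites, file.path(out, "loo_sites.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  if (config$predict_map && !is.null(res$sim$layers)) {
    stage_msg("predict_map", seed)
    bt <- base_terms(spec$abundance_terms)
    lay <- res$sim$layers[intersect(bt, names(res$sim$layers))]
    if (length(lay) == length(bt)) {
      std <- res$sim$standardization
      map <- predict_abundance(fit, lay, centers = std$centers, scales = std$scales)
      write_ascii_grid(map, file.path(out, "abundance_map.asc"))
      res$abundance_map <- map
    }
  }

  if (config$multistate && !is.null(data$states)) {
    stage_msg("multistate", seed)
    res$multistate <- purrr::imap(data$states, function(st, nm) {
      fit_multistate(st, X = data$X, W = data$W,
                     R_terms = "(Intercept)", seed = seed)
    })
    ms_tbl <- purrr::imap_dfr(res$multistate, function(m, nm) {
      dplyr::bind_cols(tibble::tibble(cohort = nm), glance(m))
    })
    utils::write.csv(ms_tbl, file.path(out, "multistate_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(res$sim)) {
      stage_msg("postanalysis", seed)
      cls <- cohort_landscape_summary(
        fit$site_abundance,
        conditional_occurrence(res$multistate$gravid),
        conditional_occurrence(res$multistate$juvenile),
        res$sim$temperature[c("site_id", "temp_c")])
      res$postanalysis <- cls
      utils::write.csv(cls$regressions, file.path(out, "regressions.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  }

  files <- list.files(out, full.names = TRUE)
  manifest <- data.frame(file = basename(files), md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(seed = seed, files = manifest),
                         file.path(out, "manifest.json"), auto_unbox = TRUE,
                         dataframe = "rows")
  } else {
    utils::write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  }
  invisible(res)
}
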