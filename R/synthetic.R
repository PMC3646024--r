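#' Generating ("truth") parameters for synthetic studies
#'
#' Defaults are the posterior means of the fitted field study: log-scale
#' abundance coefficients on NDVI, TPI, TWI, PRR and the TWI:PRR
#' interaction; logit-scale detection coefficients on survey date, bark
#' cover, days-since-soaking-rain (linear + quadratic) and plot temperature
#' (linear + quadratic). `sigma_p` is the SD of the plot-survey detection
#' random effect; `phi` the zero-inflation weight (0 = plain Poisson).
#' Quadratic and interaction terms are built from the already-standardized
#' linear terms (`"A^2"`, `"A:B"` in the term names).
#'
#' Stage structure: the per-individual gravid-female share is
#' `r_gravid * 0.5 * (1 - mean juvenile fraction)` — site-independent, so
#' reproductive effort is spatially flat — while the juvenile share
#' declines logistically with standardized site temperature,
#' `plogis(juvenile_intercept + juvenile_temp_slope * tempZ)`; remaining
#' adults split evenly by sex.
#'
#' @param beta named abundance coefficients (log scale); first is intercept.
#' @param alpha named detection coefficients (logit scale); first is intercept.
#' @param sigma_p SD of the plot-survey detection random effect (>= 0).
#' @param phi zero-inflation probability in [0, 1].
#' @param r_gravid probability an adult female is gravid.
#' @param juvenile_intercept,juvenile_temp_slope logit-scale juvenile-stage
#'   probability parameters (slope < 0 makes juveniles prefer cool sites).
#' @param temp_model named linear coefficients (intercept in degrees C, the
#'   rest per SD of the named standardized terrain covariate) giving the
#'   maximum surface temperature surface.
#' @return a `truth_params` list.
#' @export
truth_params <- function(
    beta = c("(Intercept)" = 0.445, NDVI = 0.422, TPI = -0.371,
             TWI = -0.326, PRR = -0.241, "TWI:PRR" = -0.283),
    alpha = c("(Intercept)" = -1.64, Date = 0.904, Bark = 0.263,
              Soak.Rain = -0.491, "Soak.Rain^2" = 0.463,
              Temp = 0.144, "Temp^2" = -0.220),
    sigma_p = 0.5, phi = 0,
    r_gravid = 0.6, juvenile_intercept = -0.4, juvenile_temp_slope = -1.2,
    temp_model = c("(Intercept)" = 28, TPI = 1.5, TWI = -1.0, PRR = 2.0)) {
  if (phi < 0 || phi > 1) stop("`phi` must be in [0, 1].", call. = FALSE)
  if (sigma_p < 0) stop("`sigma_p` must be >= 0.", call. = FALSE)
  if (r_gravid < 0 || r_gravid > 1) stop("`r_gravid` must be in [0, 1].", call. = FALSE)
  if (is.null(names(beta)) || is.null(names(alpha))) {
    stop("`beta` and `alpha` must be named coefficient vectors.", call. = FALSE)
  }
  structure(list(beta = beta, alpha = alpha, sigma_p = sigma_p, phi = phi,
                 r_gravid = r_gravid, juvenile_intercept = juvenile_intercept,
                 juvenile_temp_slope = juvenile_temp_slope,
                 temp_model = temp_model),
            class = "truth_params")
}

#' Survey design
#'
#' Defaults reproduce the field design: 135 plots of 3 m x 3 m, at least
#' 75 m apart, each surveyed 7 times.
#'
#' @param n_sites number of survey plots.
#' @param n_surveys repeat surveys per plot.
#' @param plot_side_m plot edge length, metres.
#' @param min_spacing_m minimum pairwise plot distance, metres.
#' @return a `study_design` list.
#' @export
study_design <- function(n_sites = 135, n_surveys = 7, plot_side_m = 3,
                         min_spacing_m = 75) {
  if (n_sites < 1 || n_surveys < 1) {
    stop("`n_sites` and `n_surveys` must be >= 1.", call. = FALSE)
  }
  if (min_spacing_m < 0) stop("`min_spacing_m` must be >= 0.", call. = FALSE)
  structure(list(n_sites = as.integer(n_sites), n_surveys = as.integer(n_surveys),
                 plot_side_m = plot_side_m, min_spacing_m = min_spacing_m),
            class = "study_design")
}

child_seed <- function(seed, stage) {
  (as.integer(seed) %% 94906249L + 1009L * as.integer(stage)) %% 2147483647L
}

smooth_passes <- function(m, halfwidth, passes = 3) {
  off <- expand.grid(dr = -halfwidth:halfwidth, dc = -halfwidth:halfwidth)
  for (i in seq_len(passes)) {
    m <- .focal_mean_cpp(m, as.integer(off$dr), as.integer(off$dc))
  }
  m
}

#' Generate a synthetic ridge-and-ravine DEM
#'
#' A seeded smoothed random field: broad-scale smoothed noise supplies
#' ridge/valley structure and a finer-scale component supplies local
#' relief; `roughness` scales the whole field (0 gives a flat DEM). Output
#' is deterministic for a given seed.
#'
#' @param extent_cells `c(nrow, ncol)`, each >= 64.
#' @param cell_m cell size, metres.
#' @param roughness nonnegative amplitude multiplier.
#' @param seed integer RNG seed.
#' @param base_elevation_m constant added to the field.
#' @return a `terra_raster` DEM.
#' @export
generate_landscape <- function(extent_cells = c(128, 128), cell_m = 3,
                               roughness = 1, seed = 1,
                               base_elevation_m = 200) {
  if (length(extent_cells) != 2 || any(extent_cells < 64)) {
    stop("`extent_cells` must be two counts, each >= 64.", call. = FALSE)
  }
  if (cell_m <= 0) stop("`cell_m` must be positive.", call. = FALSE)
  if (roughness < 0) stop("`roughness` must be >= 0.", call. = FALSE)
  nr <- as.integer(extent_cells[1]); nc <- as.integer(extent_cells[2])
  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 1L))
  broad <- smooth_passes(matrix(stats::rnorm(nr * nc), nr, nc),
                         halfwidth = max(4L, min(nr, nc) %/% 10), passes = 3)
  fine <- smooth_passes(matrix(stats::rnorm(nr * nc), nr, nc),
                        halfwidth = 2L, passes = 2)
  scl <- function(m) if (stats::sd(m) > 0) (m - mean(m)) / stats::sd(m) else m * 0
  z <- roughness * (12 * scl(broad) + 1.5 * scl(fine)) + base_elevation_m
  restore_seed(old)
  terra_raster(z, cell_m, origin = c(0, nr * cell_m), crs_tag = "local-m")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) return(invisible())
  assign(".Random.seed", old, envir = globalenv())
  invisible()
}

#' Place survey plots with a minimum-spacing constraint
#'
#' Rejection sampling of plot centres uniformly over the DEM interior,
#' keeping candidates at least `min_spacing_m` from every accepted plot.
#'
#' @param dem a `terra_raster`.
#' @param design a [study_design()].
#' @param seed integer RNG seed.
#' @param max_attempts rejection-sampling attempt cap.
#' @return tibble: `site_id`, `x`, `y` (metres).
#' @export
sample_plots <- function(dem, design = study_design(), seed = 1,
                         max_attempts = 1e5) {
  stopifnot_raster(dem, "dem")
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  w <- nc * dem$cell_size; h <- nr * dem$cell_size
  margin <- design$plot_side_m / 2
  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 2L))
  xs <- ys <- numeric(0)
  attempts <- 0L
  while (length(xs) < design$n_sites) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      restore_seed(old)
      stop(sprintf("could not place %d plots at %.0f m spacing in %d attempts.",
                   design$n_sites, design$min_spacing_m, as.integer(max_attempts)),
           call. = FALSE)
    }
    cx <- dem$origin[1] + stats::runif(1, margin, w - margin)
    cy <- dem$origin[2] - stats::runif(1, margin, h - margin)
    if (length(xs) == 0 ||
        all((xs - cx)^2 + (ys - cy)^2 >= design$min_spacing_m^2)) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  }
  restore_seed(old)
  tibble::tibble(site_id = sprintf("site_%03d", seq_along(xs)), x = xs, y = ys)
}

check_standardized <- function(X, cols, tol = 0.01) {
  for (cl in cols) {
    v <- X[[cl]]
    s <- stats::sd(v)
    if (abs(mean(v)) > tol || (s > 0 && abs(s - 1) > tol)) {
      stop(sprintf("covariate `%s` is not standardized (mean %.3f, sd %.3f).",
                   cl, mean(v), s), call. = FALSE)
    }
  }
  invisible(TRUE)
}

base_terms <- function(terms) {
  terms <- setdiff(terms, "(Intercept)")
  unique(unlist(lapply(terms, function(t) {
    t <- sub("\\^2$", "", t)
    strsplit(t, ":", fixed = TRUE)[[1]]
  })))
}

#' Build a model design matrix from named terms
#'
#' Terms reference columns of `data`; `"A^2"` is the square of the
#' standardized column A and `"A:B"` the product of standardized columns —
#' neither is re-standardized, keeping all terms on the scale of the linear
#' covariates.
#'
#' @param data data frame of (standardized) covariate columns.
#' @param terms character vector of term names, `"(Intercept)"` allowed.
#' @return numeric matrix, one column per term.
#' @export
build_design_matrix <- function(data, terms) {
  n <- nrow(data)
  cols <- lapply(terms, function(t) {
    if (t == "(Intercept)") return(rep(1, n))
    if (grepl("\\^2$", t)) {
      b <- sub("\\^2$", "", t)
      if (is.null(data[[b]])) stop(sprintf("missing covariate `%s`.", b), call. = FALSE)
      return(data[[b]]^2)
    }
    if (grepl(":", t, fixed = TRUE)) {
      bs <- strsplit(t, ":", fixed = TRUE)[[1]]
      miss <- bs[!bs %in% names(data)]
      if (length(miss)) stop(sprintf("missing covariate `%s`.", miss[1]), call. = FALSE)
      return(Reduce(`*`, data[bs]))
    }
    if (is.null(data[[t]])) stop(sprintf("missing covariate `%s`.", t), call. = FALSE)
    data[[t]]
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

#' Simulate the latent population at each site
#'
#' Expected abundance is log-linear in the standardized site covariates:
#' `lambda_i = exp(x_i' beta)`; `N_i ~ Poisson(lambda_i)` or, under zero
#' inflation, `N_i = 0` with probability `phi`. Individuals are assigned
#' stages (juvenile / adult male / non-gravid female / gravid female) with
#' a juvenile probability that declines logistically in site temperature
#' and a site-independent gravid fraction among adult females.
#'
#' @param X tibble of standardized site covariates (mean 0, SD 1; columns
#'   must cover the base terms of `truth$beta`).
#' @param truth a [truth_params()].
#' @param seed integer RNG seed.
#' @param temperature optional standardized site temperature vector driving
#'   the juvenile stage probability (default 0).
#' @return tibble: `site_id`, `lambda`, `N`, `n_juvenile`, `n_adult_male`,
#'   `n_female_nongravid`, `n_gravid`.
#' @export
simulate_population <- function(X, truth = truth_params(), seed = 1,
                                temperature = NULL) {
  X <- tibble::as_tibble(X)
  bt <- base_terms(names(truth$beta))
  check_standardized(X, intersect(bt, names(X)))
  miss <- setdiff(bt, names(X))
  if (length(miss)) stop(sprintf("missing covariate `%s`.", miss[1]), call. = FALSE)
  Xab <- build_design_matrix(X, names(truth$beta))
  S <- nrow(Xab)
  if (is.null(temperature)) temperature <- rep(0, S)
  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 3L))
  lambda <- exp(drop(Xab %*% truth$beta))
  N <- stats::rpois(S, lambda)
  if (truth$phi > 0) {
    N[stats::runif(S) < truth$phi] <- 0L
  }
  # gravid share is site-independent by construction (reproductive effort is
  # spatially flat); the juvenile share declines logistically with site
  # temperature. The typical adult fraction uses the average juvenile
  # probability so the gravid share does not inherit the temperature signal.
  p_juv <- stats::plogis(truth$juvenile_intercept +
                           truth$juvenile_temp_slope * temperature)
  p_juv_bar <- stats::plogis(truth$juvenile_intercept)
  g_share <- truth$r_gravid * 0.5 * (1 - p_juv_bar)
  n_gravid <- stats::rbinom(S, N, g_share)
  n_juv <- stats::rbinom(S, N - n_gravid, p_juv)
  n_adult_rest <- N - n_gravid - n_juv
  n_female_ng <- stats::rbinom(S, n_adult_rest, 0.5)
  restore_seed(old)
  tibble::tibble(
    site_id = X[["site_id"]] %||% sprintf("site_%03d", seq_len(S)),
    lambda = lambda, N = as.integer(N),
    n_juvenile = as.integer(n_juv),
    n_adult_male = as.integer(n_adult_rest - n_female_ng),
    n_female_nongravid = as.integer(n_female_ng),
    n_gravid = as.integer(n_gravid)
  )
}

#' Simulate per-survey detection covariates
#'
#' Survey date (shared across plots, linear in survey index), bark cover
#' (plot-level, constant over surveys), days since soaking rain (shared
#' across plots per survey) and plot temperature (plot-survey), each
#' standardized over all plot-survey cells.
#'
#' @param n_sites,n_surveys design dimensions.
#' @param seed integer RNG seed.
#' @return long tibble: `site_id`, `survey`, `Date`, `Bark`, `Soak.Rain`,
#'   `Temp` (all standardized).
#' @export
make_survey_covariates <- function(n_sites, n_surveys, seed = 1) {
  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 4L))
  date_j <- seq_len(n_surveys)
  soak_j <- stats::rnorm(n_surveys)
  bark_i <- stats::rnorm(n_sites)
  g <- tidyr::expand_grid(site = seq_len(n_sites), survey = seq_len(n_surveys))
  temp <- stats::rnorm(nrow(g))
  restore_seed(old)
  z <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  tibble::tibble(
    site_id = sprintf("site_%03d", g$site),
    survey = g$survey,
    Date = z(date_j[g$survey]),
    Bark = z(bark_i[g$site]),
    Soak.Rain = z(soak_j[g$survey]),
    Temp = z(temp)
  )
}

#' Simulate repeated-count surveys (and demographic state codes)
#'
#' Detection is logit-linear in the standardized survey covariates plus a
#' plot-survey normal random effect: `p_ij = plogis(w_ij' alpha + eps_ij)`,
#' `eps_ij ~ N(0, sigma_p^2)`; counts `y_ij ~ Binomial(N_i, p_ij)`. Which
#' detected individuals belong to a demographic cohort follows a
#' hypergeometric draw from the site's stage composition, giving 0/1/2
#' observation codes per cohort (0 = nothing detected, 1 = salamanders but
#' no cohort member detected, 2 = cohort member detected).
#'
#' @param latents output of [simulate_population()].
#' @param W long tibble from [make_survey_covariates()] (standardized).
#' @param truth a [truth_params()].
#' @param seed integer RNG seed.
#' @return a `survey_dataset` (see [survey_dataset()]) whose `states` field
#'   holds the gravid-female and juvenile 0/1/2 code matrices.
#' @export
simulate_surveys <- function(latents, W, truth = truth_params(), seed = 1) {
  W <- dplyr::arrange(tibble::as_tibble(W), .data$survey, .data$site_id)
  sites <- unique(W$site_id)
  if (!identical(sort(sites), sort(latents$site_id))) {
    stop("site ids in `latents` and `W` do not match.", call. = FALSE)
  }
  S <- length(sites); J <- max(W$survey)
  if (nrow(W) != S * J) stop("`W` must have one row per site x survey.", call. = FALSE)
  lat <- latents[match(sites, latents$site_id), ]
  at <- base_terms(names(truth$alpha))
  check_standardized(W, intersect(at, names(W)))
  Wm <- build_design_matrix(W, names(truth$alpha))
  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 5L))
  eta <- drop(Wm %*% truth$alpha)
  eps <- if (truth$sigma_p > 0) stats::rnorm(S * J, 0, truth$sigma_p) else 0
  p <- stats::plogis(eta + eps)
  Nrep <- rep(lat$N, times = J)
  y <- stats::rbinom(S * J, Nrep, p)
  # cohort detections among the y detected individuals
  draw_states <- function(n_target) {
    k <- rep(n_target, times = J)
    got <- stats::rhyper(S * J, m = k, n = Nrep - k, k = y)
    code <- ifelse(y == 0, 0L, ifelse(got > 0, 2L, 1L))
    matrix(code, nrow = S, ncol = J, dimnames = list(sites, NULL))
  }
  st_g <- draw_states(lat$n_gravid)
  st_j <- draw_states(lat$n_juvenile)
  restore_seed(old)
  ym <- matrix(as.integer(y), nrow = S, ncol = J, dimnames = list(sites, NULL))
  survey_dataset(y = ym, X = NULL, W = W,
                 states = list(gravid = st_g, juvenile = st_j),
                 truth_p = matrix(p, S, J))
}

#' Repeated-count survey dataset
#'
#' Container for the counts, covariates and optional demographic state
#' codes handed to the model-fitting functions.
#'
#' @param y S x J integer count matrix (rownames = site ids; NA = missed
#'   survey).
#' @param X tibble of standardized site covariates (`site_id` + columns),
#'   or NULL.
#' @param W long tibble of standardized survey covariates (`site_id`,
#'   `survey`, columns), or NULL.
#' @param states optional list of S x J 0/1/2 matrices per cohort.
#' @param truth_p optional matrix of generating detection probabilities.
#' @return a `survey_dataset`.
#' @export
survey_dataset <- function(y, X = NULL, W = NULL, states = NULL, truth_p = NULL) {
  y <- as.matrix(y)
  if (any(!is.na(y) & y < 0)) stop("counts must be nonnegative.", call. = FALSE)
  if (is.null(rownames(y))) rownames(y) <- sprintf("site_%03d", seq_len(nrow(y)))
  structure(list(y = y, X = X, W = W, states = states, truth_p = truth_p,
                 site_ids = rownames(y)),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("<survey_dataset> %d sites x %d surveys, %d counts observed (total %d)\n",
              nrow(x$y), ncol(x$y), sum(!is.na(x$y)), sum(x$y, na.rm = TRUE)))
  invisible(x)
}

#' Simulate a complete synthetic study
#'
#' Chains the generators end to end: landscape, terrain covariate stack,
#' plot placement, covariate extraction and standardization, a parametric
#' maximum-temperature surface, the latent population and the repeated
#' surveys. With `landscape = FALSE` the terrain stage is skipped and site
#' covariates are drawn as independent standard normals (the model's own
#' generating assumption), which is the fast path for simulation studies.
#'
#' @param design a [study_design()].
#' @param truth a [truth_params()].
#' @param seed integer RNG seed.
#' @param landscape use a generated DEM + terrain covariates (TRUE) or
#'   direct standard-normal site covariates (FALSE).
#' @param extent_cells,cell_m passed to [generate_landscape()].
#' @return list: `data` (a `survey_dataset` with `X` filled), `latents`,
#'   `truth`, `design`, `sites`, `temperature`, and (if `landscape`) `dem`
#'   and `layers`.
#' @export
simulate_study <- function(design = study_design(), truth = truth_params(),
                           seed = 1, landscape = FALSE,
                           extent_cells = c(128, 128), cell_m = 12) {
  S <- design$n_sites
  if (landscape) {
    dem <- generate_landscape(extent_cells, cell_m, seed = seed)
    layers <- terrain_covariates(dem)
    sites <- sample_plots(dem, design, seed = seed)
    old <- .Random.seed_exists()
    set.seed(child_seed(seed, 6L))
    # canopy greenness: tracks shade (low radiation) plus smooth local noise
    prr_v <- layers$PRR$values
    noise <- smooth_passes(matrix(stats::rnorm(length(prr_v)), nrow(prr_v)), 3L, 2)
    noise <- if (stats::sd(noise) > 0) (noise - mean(noise)) / stats::sd(noise) else noise
    ndvi_v <- 0.7 - 0.1 * (prr_v - mean(prr_v)) / stats::sd(prr_v) + 0.05 * noise
    layers$NDVI <- raster_like(dem, ndvi_v)
    restore_seed(old)
    raw <- extract_covariates(layers[c("NDVI", "TPI", "TWI", "PRR")], sites)
    std <- standardize_covariates(raw, cols = c("NDVI", "TPI", "TWI", "PRR"))
    X <- std$data
    tm <- truth$temp_model
    old <- .Random.seed_exists()
    set.seed(child_seed(seed, 9L))
    # terrain-driven maximum surface temperature plus residual variation the
    # terrain terms do not explain (a fitted logger surface is never exact)
    tempC <- drop(build_design_matrix(X, names(tm)) %*% tm) +
      stats::rnorm(S, 0, 1.5)
    restore_seed(old)
    tempZ <- as.numeric(scale(tempC))
  } else {
    dem <- layers <- NULL
    old <- .Random.seed_exists()
    set.seed(child_seed(seed, 6L))
    bt <- base_terms(names(truth$beta))
    X <- tibble::tibble(site_id = sprintf("site_%03d", seq_len(S)))
    for (nm in bt) X[[nm]] <- as.numeric(scale(stats::rnorm(S)))
    tempZ <- as.numeric(scale(stats::rnorm(S)))
    tempC <- truth$temp_model[["(Intercept)"]] + 2.5 * tempZ
    sites <- tibble::tibble(site_id = X$site_id, x = NA_real_, y = NA_real_)
    restore_seed(old)
  }
  latents <- simulate_population(X, truth, seed = seed, temperature = tempZ)
  W <- make_survey_covariates(S, design$n_surveys, seed = seed)
  ds <- simulate_surveys(latents, W, truth, seed = seed)
  ds$X <- X
  out <- list(data = ds, latents = latents, truth = truth, design = design,
              sites = sites,
              temperature = tibble::tibble(site_id = X$site_id,
                                           temp_c = tempC, temp_z = tempZ))
  if (landscape) {
    out$dem <- dem; out$layers <- layers
    out$standardization <- std[c("centers", "scales")]
  }
  out
}
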