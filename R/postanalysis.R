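#' Convert plot abundance to per-square-metre density
#'
#' @param plot_abundance abundance on a plot (vectorized).
#' @param plot_area_m2 plot area in square metres (default 9, a 3 m plot).
#' @return density per square metre.
#' @export
density_from_abundance <- function(plot_abundance, plot_area_m2 = 9) {
  if (any(plot_area_m2 <= 0)) stop("`plot_area_m2` must be positive.", call. = FALSE)
  plot_abundance / plot_area_m2
}

#' Simple linear regression summary
#'
#' Ordinary least squares of `y` on `x` with the F statistic recovered
#' from `R^2`: `F = (R^2/df1) / ((1 - R^2)/df2)`, `df1 = 1`. The default
#' residual convention is `df2 = n - 2`; `df_convention = "n_minus_1"`
#' mirrors reports that print `df2 = n - 1`.
#'
#' @param x,y numeric vectors, `n >= 3`, `x` not constant.
#' @param df_convention `"residual"` (n - 2) or `"n_minus_1"`.
#' @return tibble: slope, intercept, F, df1, df2, r_squared, p_value, n.
#' @export
regression_summary <- function(x, y, df_convention = c("residual", "n_minus_1")) {
  df_convention <- match.arg(df_convention)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations.", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` is constant; regression is degenerate.", call. = FALSE)
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0 # constant response: no variance explained
  df2 <- if (df_convention == "residual") n - 2L else n - 1L
  Fstat <- if (r2 >= 1) Inf else (r2 / 1) / ((1 - r2) / df2)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    statistic = Fstat, df1 = 1L, df2 = df2,
    r_squared = r2,
    p_value = stats::pf(Fstat, 1, df2, lower.tail = FALSE),
    n = n
  )
}

#' Test whether two groups share a regression slope
#'
#' Pooled model `y ~ x * group`; the reported p-value is for the
#' group-by-x interaction.
#'
#' @param x,y numeric vectors stacked over both groups.
#' @param group factor-like group labels (2 levels).
#' @return tibble: interaction estimate, se, statistic, p_value.
#' @export
slope_interaction_test <- function(x, y, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("`group` must have exactly 2 levels.", call. = FALSE)
  fit <- stats::lm(y ~ x * group)
  cf <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  row <- grep(":", rownames(cf))
  tibble::tibble(estimate = cf[row, 1], se = cf[row, 2],
                 statistic = cf[row, 3], p_value = cf[row, 4])
}

#' Cohort occurrence vs abundance and temperature across the landscape
#'
#' Joins the per-site abundance estimates, maximum-temperature values and
#' the fitted conditional occurrence of each cohort, then runs the summary
#' regressions: each cohort's occurrence against abundance and against
#' temperature, abundance against temperature, and the two cohort-by-
#' predictor slope-interaction tests.
#'
#' @param abundance tibble with `site_id`, `mean` (e.g. an `nmix_fit`'s
#'   `site_abundance`).
#' @param gravid,juvenile tibbles from [conditional_occurrence()].
#' @param temperature tibble with `site_id` and `temp_c` (or a single
#'   numeric column besides `site_id`).
#' @param df_convention passed to [regression_summary()].
#' @return list: `table` (per-site tibble), `regressions` (one row per
#'   fitted regression), `interactions` (one row per interaction test).
#' @export
cohort_landscape_summary <- function(abundance, gravid, juvenile, temperature,
                                     df_convention = "residual") {
  tcol <- setdiff(names(temperature), "site_id")[1]
  tab <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(abundance), "site_id", abundance = "mean"),
    dplyr::select(tibble::as_tibble(temperature), "site_id", temp = dplyr::all_of(tcol)),
    by = "site_id")
  tab <- dplyr::inner_join(tab, dplyr::select(gravid, "site_id", R_gravid = "R_hat"),
                           by = "site_id")
  tab <- dplyr::inner_join(tab, dplyr::select(juvenile, "site_id", R_juvenile = "R_hat"),
                           by = "site_id")
  orphans <- setdiff(unique(c(abundance$site_id, gravid$site_id,
                              juvenile$site_id, temperature$site_id)),
                     tab$site_id)
  if (length(orphans)) {
    stop(sprintf("site keys do not align; orphans: %s",
                 paste(utils::head(orphans, 5), collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) < 3) stop("need at least 3 matched sites.", call. = FALSE)
  reg <- function(xv, yv, label) {
    dplyr::bind_cols(tibble::tibble(regression = label),
                     regression_summary(xv, yv, df_convention))
  }
  regressions <- dplyr::bind_rows(
    reg(tab$abundance, tab$R_gravid, "gravid_vs_abundance"),
    reg(tab$abundance, tab$R_juvenile, "juvenile_vs_abundance"),
    reg(tab$temp, tab$R_gravid, "gravid_vs_temperature"),
    reg(tab$temp, tab$R_juvenile, "juvenile_vs_temperature"),
    reg(tab$temp, tab$abundance, "abundance_vs_temperature")
  )
  long <- tidyr::pivot_longer(tab, c("R_gravid", "R_juvenile"),
                              names_to = "cohort", values_to = "occurrence")
  interactions <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(test = "cohort_x_abundance"),
                     slope_interaction_test(long$abundance, long$occurrence, long$cohort)),
    dplyr::bind_cols(tibble::tibble(test = "cohort_x_temperature"),
                     slope_interaction_test(long$temp, long$occurrence, long$cohort))
  )
  list(table = tab, regressions = regressions, interactions = interactions)
}

#' Figure-style cohort occurrence plot
#'
#' @param summary output of [cohort_landscape_summary()].
#' @param x `"abundance"` or `"temp"`.
#' @return a ggplot of both cohorts' occurrence against the predictor.
#' @export
plot_cohort_occurrence <- function(summary, x = c("abundance", "temp")) {
  x <- match.arg(x)
  long <- tidyr::pivot_longer(summary$table, c("R_gravid", "R_juvenile"),
                              names_to = "cohort", values_to = "occurrence")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[x]], y = .data$occurrence,
                                     colour = .data$cohort)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = x, y = "conditional occurrence probability") +
    ggplot2::theme_minimal()
}
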