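pad_replicate <- function(m) {
  m <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
}

#' Slope, aspect, northness and eastness from a DEM
#'
#' Horn's 3x3 finite-difference estimator on a north-up grid (row 1 =
#' northernmost). Aspect is the downslope azimuth in degrees clockwise from
#' north and is undefined (NA) on flat cells; northness = cos(aspect) runs
#' from 1 (north-facing) to -1 (south-facing) and eastness = sin(aspect)
#' from 1 (east) to -1 (west). Edge cells use replicate padding.
#'
#' @param dem a `terra_raster` of elevations in metres.
#' @return list of `terra_raster`s: `slope` (degrees), `aspect` (degrees),
#'   `northness`, `eastness`.
#' @export
slope_aspect <- function(dem) {
  stopifnot_raster(dem, "dem")
  v <- dem$values
  if (nrow(v) < 3 || ncol(v) < 3) stop("DEM must be at least 3x3 cells.", call. = FALSE)
  if (all(is.na(v))) stop("DEM has no valid cells.", call. = FALSE)
  h <- dem$cell_size
  p <- pad_replicate(v)
  nr <- nrow(v); nc <- ncol(v)
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  a <- p[ri - 1, ci - 1]; b <- p[ri - 1, ci]; cc <- p[ri - 1, ci + 1]
  d <- p[ri, ci - 1];                         f <- p[ri, ci + 1]
  g <- p[ri + 1, ci - 1]; hh <- p[ri + 1, ci]; i2 <- p[ri + 1, ci + 1]
  dzdx <- ((cc + 2 * f + i2) - (a + 2 * d + g)) / (8 * h)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * hh + i2)) / (8 * h) # northward
  slope_rad <- atan(sqrt(dzdx^2 + dzdy^2))
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  flat <- slope_rad == 0
  aspect[flat] <- NA_real_
  list(
    slope = raster_like(dem, slope_rad * 180 / pi),
    aspect = raster_like(dem, aspect),
    northness = raster_like(dem, cos(aspect * pi / 180)),
    eastness = raster_like(dem, sin(aspect * pi / 180))
  )
}

circle_offsets <- function(radius_cells, exclude_center = TRUE) {
  k <- floor(radius_cells)
  g <- expand.grid(dr = -k:k, dc = -k:k)
  keep <- sqrt(g$dr^2 + g$dc^2) <= radius_cells
  if (exclude_center) keep <- keep & !(g$dr == 0 & g$dc == 0)
  g[keep, , drop = FALSE]
}

#' Topographic position index
#'
#' Cell elevation minus the mean elevation within a circular neighbourhood
#' (centre excluded). Negative values mark ravines, positive values ridges.
#'
#' @param dem a `terra_raster`.
#' @param radius_m neighbourhood radius in metres (default 90 m).
#' @return a `terra_raster` of TPI values.
#' @export
tpi <- function(dem, radius_m = 90) {
  stopifnot_raster(dem, "dem")
  if (radius_m < dem$cell_size) {
    stop("`radius_m` must be at least one cell.", call. = FALSE)
  }
  off <- circle_offsets(radius_m / dem$cell_size, exclude_center = TRUE)
  nb <- .focal_mean_cpp(dem$values, as.integer(off$dr), as.integer(off$dc))
  raster_like(dem, dem$values - nb)
}

#' Hillshade (relative illumination) for a sun position
#'
#' `H = cos(zenith) cos(slope) + sin(zenith) sin(slope) cos(azimuth - aspect)`
#' clipped below at 0; flat ground evaluates to `sin(altitude)`.
#'
#' @param dem a `terra_raster`.
#' @param azimuth_deg solar azimuth, degrees clockwise from north.
#' @param altitude_deg solar altitude above the horizon, in (0, 90].
#' @return a `terra_raster` with values in [0, 1].
#' @export
hillshade <- function(dem, azimuth_deg, altitude_deg) {
  stopifnot_raster(dem, "dem")
  if (altitude_deg <= 0 || altitude_deg > 90) {
    stop("`altitude_deg` must be in (0, 90].", call. = FALSE)
  }
  sa <- slope_aspect(dem)
  zen <- (90 - altitude_deg) * pi / 180
  sl <- sa$slope$values * pi / 180
  asp <- sa$aspect$values * pi / 180
  rel <- cos(azimuth_deg * pi / 180 - asp)
  rel[is.na(asp)] <- 0 # flat: aspect term vanishes
  h <- cos(zen) * cos(sl) + sin(zen) * sin(sl) * rel
  h[!is.na(h) & h < 0] <- 0
  raster_like(dem, h)
}

#' Solar position (declination/hour-angle approximation)
#'
#' Local solar time; Cooper declination; no atmospheric refraction. Azimuth
#' is degrees clockwise from north.
#'
#' @param latitude_deg latitude in degrees, [-90, 90].
#' @param month,day calendar date (non-leap year).
#' @param hour local solar hour in [0, 24).
#' @return tibble with `azimuth_deg`, `altitude_deg`.
#' @export
solar_position <- function(latitude_deg, month, day, hour) {
  if (any(latitude_deg < -90 | latitude_deg > 90)) {
    stop("`latitude_deg` must be in [-90, 90].", call. = FALSE)
  }
  cum <- c(0, 31, 59, 90, 120, 151, 181, 212, 243, 273, 304, 334)
  doy <- cum[month] + day
  dec <- 23.45 * sin(2 * pi * (284 + doy) / 365) * pi / 180
  lat <- latitude_deg * pi / 180
  H <- (hour - 12) * 15 * pi / 180
  sinalt <- sin(lat) * sin(dec) + cos(lat) * cos(dec) * cos(H)
  alt <- asin(pmin(1, pmax(-1, sinalt)))
  az <- atan2(sin(H), cos(H) * sin(lat) - tan(dec) * cos(lat)) + pi
  tibble::tibble(azimuth_deg = (az * 180 / pi) %% 360,
                 altitude_deg = alt * 180 / pi)
}

#' Solar schedule constructor
#'
#' @param latitude_deg site latitude in degrees.
#' @param dates data frame with `month` and `day` columns.
#' @param hours local solar hours in [0, 24).
#' @return a `solar_schedule` list.
#' @export
solar_schedule <- function(latitude_deg,
                           dates = expand.grid(month = 4:10, day = c(1L, 15L)),
                           hours = 0:23) {
  if (latitude_deg < -90 || latitude_deg > 90) {
    stop("`latitude_deg` must be in [-90, 90].", call. = FALSE)
  }
  if (any(hours < 0 | hours >= 24)) stop("`hours` must lie in [0, 24).", call. = FALSE)
  if (nrow(dates) < 1) stop("schedule needs at least one date.", call. = FALSE)
  structure(list(latitude_deg = latitude_deg,
                 dates = tibble::as_tibble(dates), hours = hours),
            class = "solar_schedule")
}

#' Potential relative radiation
#'
#' Sums hillshade over every (date, hour) of a solar schedule, skipping
#' timestamps with the sun at or below the horizon. The default schedule is
#' every hour of the 1st and 15th of April through October.
#'
#' @param dem a `terra_raster`.
#' @param schedule a [solar_schedule()].
#' @return a `terra_raster` of summed relative illumination.
#' @export
prr <- function(dem, schedule = solar_schedule(38.78)) {
  stopifnot_raster(dem, "dem")
  grid <- tidyr::expand_grid(schedule$dates, hour = schedule$hours)
  pos <- solar_position(schedule$latitude_deg, grid$month, grid$day, grid$hour)
  pos <- pos[pos$altitude_deg > 0, , drop = FALSE]
  acc <- matrix(0, nrow(dem$values), ncol(dem$values))
  for (t in seq_len(nrow(pos))) {
    acc <- acc + hillshade(dem, pos$azimuth_deg[t], pos$altitude_deg[t])$values
  }
  raster_like(dem, acc)
}

#' Topographic wetness index
#'
#' `TWI = ln(a / tan(slope))` with specific catchment area `a` from D8 flow
#' accumulation on a priority-flood pit-filled DEM and slope floored at 0.1
#' degree. With `insolation = c(azimuth, altitude)`, each cell's
#' accumulation weight is scaled by `1 - hillshade` at that sun position so
#' shaded (wetter-staying) contributing area counts more; the default is
#' unweighted.
#'
#' @param dem a `terra_raster`.
#' @param insolation optional `c(azimuth_deg, altitude_deg)`.
#' @return a `terra_raster` of TWI values.
#' @export
twi <- function(dem, insolation = NULL) {
  stopifnot_raster(dem, "dem")
  filled <- .pitfill_cpp(dem$values)
  wts <- matrix(1, nrow(dem$values), ncol(dem$values))
  if (!is.null(insolation)) {
    h <- hillshade(dem, insolation[1], insolation[2])$values
    wts <- 1 - h
    wts[wts < 1e-6] <- 1e-6
  }
  acc <- .d8_accum_cpp(filled, wts)
  a <- acc * dem$cell_size # specific catchment area, m
  sl <- slope_aspect(dem)$slope$values * pi / 180
  tanb <- pmax(tan(sl), tan(0.1 * pi / 180))
  raster_like(dem, log(a / tanb))
}

#' Surface curvature and distance to stream
#'
#' Curvature is the negative 3x3 Laplacian of the DEM scaled per 100 m
#' (convex ridges positive, concave ravines negative). Streams are cells
#' whose D8 accumulation meets `stream_threshold_cells`; distance is
#' Euclidean, in metres, to the nearest stream cell.
#'
#' @param dem a `terra_raster`.
#' @param stream_threshold_cells accumulation (cells) defining a stream.
#' @return list of `terra_raster`s: `curvature`, `distance_to_stream`.
#' @export
auxiliary_surfaces <- function(dem, stream_threshold_cells = 500) {
  stopifnot_raster(dem, "dem")
  if (stream_threshold_cells < 1) stop("`stream_threshold_cells` must be >= 1.", call. = FALSE)
  v <- dem$values; h <- dem$cell_size
  p <- pad_replicate(v)
  nr <- nrow(v); nc <- ncol(v)
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  lap <- (p[ri - 1, ci] + p[ri + 1, ci] + p[ri, ci - 1] + p[ri, ci + 1] - 4 * v) / h^2
  curvature <- raster_like(dem, -lap * 100)
  filled <- .pitfill_cpp(v)
  acc <- .d8_accum_cpp(filled, matrix(1, nr, nc))
  stream <- which(!is.na(acc) & acc >= stream_threshold_cells, arr.ind = TRUE)
  if (nrow(stream) == 0) {
    warning("no cell reaches the stream accumulation threshold; distance raster is all NA.")
    dist <- raster_like(dem, matrix(NA_real_, nr, nc))
  } else {
    d <- .dist_to_targets_cpp(nr, nc, as.integer(stream[, 1] - 1L),
                              as.integer(stream[, 2] - 1L))
    dist <- raster_like(dem, d * h)
  }
  list(curvature = curvature, distance_to_stream = dist)
}

#' Focal (moving-window) mean
#'
#' Mean over a square window of side `window_m`, nodata-aware; edge cells
#' average over the in-bounds part of the window (shrink-to-valid).
#'
#' @param r a `terra_raster`.
#' @param window_m window side length in metres (9 m = 3x3 cells at 3 m).
#' @return a `terra_raster`.
#' @export
focal_mean <- function(r, window_m = 9) {
  stopifnot_raster(r)
  if (window_m < r$cell_size) stop("`window_m` must be at least one cell.", call. = FALSE)
  k <- max(0L, floor(window_m / r$cell_size / 2))
  off <- expand.grid(dr = -k:k, dc = -k:k)
  raster_like(r, .focal_mean_cpp(r$values, as.integer(off$dr), as.integer(off$dc)))
}

resample_nearest <- function(r, cell_size) {
  stopifnot_raster(r)
  nr_new <- max(1L, round(nrow(r$values) * r$cell_size / cell_size))
  nc_new <- max(1L, round(ncol(r$values) * r$cell_size / cell_size))
  xs <- r$origin[1] + (seq_len(nc_new) - 0.5) * cell_size
  ys <- r$origin[2] - (seq_len(nr_new) - 0.5) * cell_size
  src_c <- pmin(ncol(r$values), pmax(1L, floor((xs - r$origin[1]) / r$cell_size) + 1L))
  src_r <- pmin(nrow(r$values), pmax(1L, floor((r$origin[2] - ys) / r$cell_size) + 1L))
  terra_raster(r$values[src_r, src_c, drop = FALSE], cell_size, r$origin,
               r$nodata, r$crs_tag)
}

#' Mean NDVI from red/near-infrared band pairs
#'
#' Per date, `NDVI = (NIR - Red) / (NIR + Red)`; dates are averaged and the
#' result resampled (nearest neighbour) to `target_cell_m`. Cells where
#' `NIR + Red = 0` are NA.
#'
#' @param bands list of `list(red = , nir = )` raster pairs (one per date).
#' @param target_cell_m output cell size in metres (NULL keeps the input grid).
#' @return a `terra_raster` of mean NDVI in [-1, 1].
#' @export
ndvi <- function(bands, target_cell_m = NULL) {
  if (!is.null(bands$red)) bands <- list(bands)
  if (length(bands) < 1) stop("at least one red/NIR date is required.", call. = FALSE)
  layers <- lapply(bands, function(b) {
    stopifnot_raster(b$red, "red"); stopifnot_raster(b$nir, "nir")
    if (!same_grid(b$red, b$nir)) stop("red and NIR bands are not co-registered.", call. = FALSE)
    denom <- b$nir$values + b$red$values
    out <- (b$nir$values - b$red$values) / denom
    out[!is.na(denom) & denom == 0] <- NA_real_
    out
  })
  mean_ndvi <- Reduce(`+`, layers) / length(layers)
  r <- raster_like(bands[[1]]$red, mean_ndvi)
  if (!is.null(target_cell_m)) r <- resample_nearest(r, target_cell_m)
  r
}

#' Standardize covariate columns
#'
#' Centres each column to mean 0 and scales to sample SD 1 (n - 1), the
#' scaling applied to every covariate before model fitting. Centres and
#' scales are returned so new data (e.g. prediction rasters) can be put on
#' the fitted scale.
#'
#' @param data data frame of numeric covariate columns.
#' @param cols columns to standardize (default: all numeric columns).
#' @return list: `data` (tibble), `centers`, `scales` (named vectors).
#' @export
standardize_covariates <- function(data, cols = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(cols)) cols <- names(data)[vapply(data, is.numeric, logical(1))]
  centers <- scales <- stats::setNames(numeric(length(cols)), cols)
  for (cl in cols) {
    v <- data[[cl]]
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0 || length(unique(stats::na.omit(v))) < 2) {
      stop(sprintf("covariate `%s` is constant; cannot standardize.", cl), call. = FALSE)
    }
    m <- mean(v, na.rm = TRUE)
    data[[cl]] <- (v - m) / s
    centers[cl] <- m; scales[cl] <- s
  }
  list(data = data, centers = centers, scales = scales)
}

#' Derive the full covariate stack from a DEM
#'
#' Convenience wrapper producing the standard microclimate surfaces (slope,
#' northness/eastness, TPI, TWI, PRR, curvature, distance to stream), each
#' smoothed with a 9 m x 9 m focal mean before use.
#'
#' @param dem a `terra_raster`.
#' @param latitude_deg latitude for the solar schedule.
#' @param tpi_radius_m TPI neighbourhood radius.
#' @param insolation optional `c(azimuth, altitude)` for the TWI weighting.
#' @param stream_threshold_cells D8 accumulation defining streams.
#' @param smooth_window_m focal-mean window applied to every layer.
#' @return named list of `terra_raster`s.
#' @export
terrain_covariates <- function(dem, latitude_deg = 38.78, tpi_radius_m = 90,
                               insolation = NULL, stream_threshold_cells = 500,
                               smooth_window_m = 9) {
  sa <- slope_aspect(dem)
  aux <- auxiliary_surfaces(dem, stream_threshold_cells)
  layers <- list(
    slope = sa$slope, northness = sa$northness, eastness = sa$eastness,
    TPI = tpi(dem, tpi_radius_m),
    TWI = twi(dem, insolation),
    PRR = prr(dem, solar_schedule(latitude_deg)),
    curvature = aux$curvature,
    dist_stream = aux$distance_to_stream
  )
  # a sub-cell window means the grid is already coarser than the smoothing
  # scale; smoothing is then the identity
  if (smooth_window_m < dem$cell_size) return(layers)
  lapply(layers, focal_mean, window_m = smooth_window_m)
}

#' Extract covariate layers at plot locations
#'
#' @param layers named list of `terra_raster`s on a common grid.
#' @param sites tibble with `site_id`, `x`, `y` (metres, raster coordinates).
#' @return tibble: `site_id` plus one column per layer.
#' @export
extract_covariates <- function(layers, sites) {
  out <- tibble::tibble(site_id = sites$site_id)
  for (nm in names(layers)) {
    out[[nm]] <- extract_at_xy(layers[[nm]], sites$x, sites$y)
  }
  out
}
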