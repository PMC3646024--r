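test_that("slope and aspect recover known planes", {
  sa <- slope_aspect(flat_dem())
  expect_true(all(sa$slope$values == 0))
  expect_true(all(is.na(sa$aspect$values)))

  # z = -y: ground falls towards the north -> north-facing, northness 1
  n <- 10
  v <- matrix(rep(seq_len(n) * 3, n), n, n) # row 1 (north) lowest
  north <- terra_raster(v, cell_size = 3)
  sa <- slope_aspect(north)
  inner <- sa$aspect$values[2:(n - 1), 2:(n - 1)]
  expect_true(all(abs(inner - 0) < 1e-10 | abs(inner - 360) < 1e-10))
  expect_true(all(abs(sa$northness$values[2:(n - 1), 2:(n - 1)] - 1) < 1e-10))

  # dz/dx = 1 at 3 m cells -> 45 degrees (interior of an east-rising ramp)
  v <- matrix(rep(seq_len(n) * 3, each = n), n, n)
  ramp <- terra_raster(v, cell_size = 3)
  sa <- slope_aspect(ramp)
  expect_equal(unname(sa$slope$values[5, 5]), 45, tolerance = 1e-10)
  # downslope west -> eastness -1
  expect_equal(unname(sa$eastness$values[5, 5]), -1, tolerance = 1e-10)
})

test_that("TPI is zero on flat ground, signs ridges/ravines, matches a brute-force oracle", {
  expect_true(all(tpi(flat_dem(11), 9)$values == 0))

  bump <- flat_dem(11)
  bump$values[6, 6] <- 110
  t1 <- tpi(bump, 9)
  expect_gt(t1$values[6, 6], 0)
  expect_lte(max(t1$values[5:7, 5:7][-5]), 0)

  set.seed(7)
  r <- terra_raster(matrix(rnorm(25), 5, 5), cell_size = 3)
  got <- tpi(r, radius_m = 6) # 2-cell radius
  oracle <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    s <- 0; n <- 0
    for (di in -2:2) for (dj in -2:2) {
      if (di == 0 && dj == 0) next
      if (sqrt(di^2 + dj^2) > 2) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > 5 || jj < 1 || jj > 5) next
      s <- s + r$values[ii, jj]; n <- n + 1
    }
    oracle[i, j] <- r$values[i, j] - s / n
  }
  expect_equal(got$values, oracle, tolerance = 1e-12)

  expect_error(tpi(r, radius_m = 1), "at least one cell")
})

test_that("hillshade has the closed form on flat ground and clips at zero", {
  expect_true(all(abs(hillshade(flat_dem(), 180, 90)$values - 1) < 1e-12))
  h <- hillshade(flat_dem(), 178.3, 65.3)
  expect_true(all(abs(h$values - sin(65.3 * pi / 180)) < 1e-12))
  # steep slope facing directly away from a low sun -> fully shaded
  away <- plane_dem(slope_deg = 60, facing = "north")
  h <- hillshade(away, 180, 20)
  expect_true(all(h$values[3:10, 3:10] == 0))
  expect_error(hillshade(flat_dem(), 180, 0), "altitude")
})

test_that("PRR is constant on flat ground, favours south faces, reduces to hillshade", {
  sched <- solar_schedule(38.78)
  p <- prr(flat_dem(), sched)
  expect_lt(diff(range(p$values)), 1e-9)

  south <- prr(plane_dem(facing = "south"), sched)
  north <- prr(plane_dem(facing = "north"), sched)
  expect_gt(mean(south$values[3:10, 3:10]), mean(north$values[3:10, 3:10]))

  # one timestamp: PRR equals hillshade at that sun position
  one <- solar_schedule(38.78, dates = data.frame(month = 6, day = 15), hours = 12)
  pos <- solar_position(38.78, 6, 15, 12)
  expect_equal(prr(plane_dem(), one)$values,
               hillshade(plane_dem(), pos$azimuth_deg, pos$altitude_deg)$values,
               tolerance = 1e-12)

  # invariant to raising the whole DEM
  d <- plane_dem()
  d2 <- raster_like(d, d$values + 55)
  expect_equal(prr(d, sched)$values, prr(d2, sched)$values, tolerance = 1e-12)
})

test_that("solar position is sane at an equinox noon", {
  pos <- solar_position(38.78, 3, 21, 12)
  expect_equal(pos$azimuth_deg, 180, tolerance = 2)
  # altitude approx 90 - latitude + declination (small near equinox)
  expect_equal(pos$altitude_deg, 90 - 38.78, tolerance = 2)
  expect_error(solar_position(100, 6, 1, 12), "latitude")
})

test_that("TWI accumulates downslope and D8 matches a hand-rolled oracle", {
  w <- twi(plane_dem(n = 12, facing = "south"))
  col <- w$values[2:11, 6]
  expect_true(all(diff(col) > 0)) # increases towards the toe of the slope

  # brute-force D8 accumulation on a small rough DEM with distinct slopes
  set.seed(11)
  nr <- 6
  v <- 30 - matrix(seq_len(nr), nr, nr) - 0.13 * matrix(seq_len(nr), nr, nr, byrow = TRUE) +
    matrix(runif(nr * nr, 0, 0.01), nr, nr)
  acc_got <- nmixterra:::.d8_accum_cpp(v, matrix(1, nr, nr))
  dirs <- expand.grid(dr = -1:1, dc = -1:1)
  dirs <- dirs[!(dirs$dr == 0 & dirs$dc == 0), ]
  dirs <- dirs[order(dirs$dr, dirs$dc), ]
  # match the C++ neighbour order: (-1,-1),(-1,0),(-1,1),(0,-1),(0,1),(1,-1),(1,0),(1,1)
  acc <- matrix(1, nr, nr)
  ord <- order(-as.vector(v))
  for (lin in ord) {
    r <- (lin - 1) %% nr + 1; c <- (lin - 1) %/% nr + 1
    best <- NULL; bests <- 0
    for (k in seq_len(nrow(dirs))) {
      rr <- r + dirs$dr[k]; cc <- c + dirs$dc[k]
      if (rr < 1 || rr > nr || cc < 1 || cc > nr) next
      s <- (v[r, c] - v[rr, cc]) / sqrt(dirs$dr[k]^2 + dirs$dc[k]^2)
      if (s > bests) { bests <- s; best <- c(rr, cc) }
    }
    if (!is.null(best)) acc[best[1], best[2]] <- acc[best[1], best[2]] + acc[r, c]
  }
  expect_equal(acc_got, acc, tolerance = 1e-12)

  # flat DEM: hillshade (hence the insolation weight) is constant, so the
  # adjusted TWI is the unadjusted TWI plus a constant
  base <- twi(flat_dem(10))
  adj <- twi(flat_dem(10), insolation = c(178.3, 65.3))
  shift <- adj$values - base$values
  expect_lt(diff(range(shift)), 1e-9)
})

test_that("pit filling drains closed depressions", {
  v <- matrix(10, 7, 7)
  v[4, 4] <- 1 # closed pit
  filled <- nmixterra:::.pitfill_cpp(v)
  expect_gte(filled[4, 4], 10)
  # already-drained plane is untouched
  p <- plane_dem(n = 7)$values
  expect_equal(nmixterra:::.pitfill_cpp(p), p, tolerance = 1e-12)
})

test_that("curvature and distance-to-stream behave on simple geometry", {
  aux <- auxiliary_surfaces(flat_dem(8), stream_threshold_cells = 3)
  expect_true(all(aux$curvature$values == 0))

  # a south-draining plane: every column is a flow line, so high-accumulation
  # cells form rows near the toe; distance grows away from them
  d <- plane_dem(n = 10, facing = "south")
  aux <- auxiliary_surfaces(d, stream_threshold_cells = 8)
  streams <- which(!is.na(aux$distance_to_stream$values) &
                     aux$distance_to_stream$values == 0, arr.ind = TRUE)
  expect_gt(nrow(streams), 0)
  # distance equals row offset to the nearest stream row times cell size
  sr <- sort(unique(streams[, 1]))
  for (r in c(1, 3)) {
    expect_equal(unname(aux$distance_to_stream$values[r, 5]),
                 min(abs(r - sr)) * d$cell_size, tolerance = 1e-9)
  }
  expect_warning(auxiliary_surfaces(flat_dem(6), stream_threshold_cells = 1e6),
                 "threshold")
})

test_that("focal mean matches arithmetic and a double-loop oracle", {
  cst <- focal_mean(flat_dem(6), 9)
  expect_true(all(cst$values == 100))

  r <- terra_raster(matrix(1:9, 3, 3, byrow = TRUE), cell_size = 3)
  expect_equal(focal_mean(r, 9)$values[2, 2], 5)

  set.seed(9)
  r <- terra_raster(matrix(rnorm(36), 6, 6), cell_size = 3)
  r$values[2, 5] <- NA
  got <- focal_mean(r, 9)
  oracle <- matrix(NA_real_, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    cells <- c()
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 6 && jj >= 1 && jj <= 6) cells <- c(cells, r$values[ii, jj])
    }
    oracle[i, j] <- mean(cells, na.rm = TRUE)
  }
  expect_equal(got$values, oracle, tolerance = 1e-12)

  # commutes with adding a constant; bounded by the window max
  shifted <- focal_mean(raster_like(r, r$values + 7), 9)
  expect_equal(shifted$values, got$values + 7, tolerance = 1e-12)
  expect_lte(max(got$values, na.rm = TRUE), max(r$values, na.rm = TRUE))
})

test_that("NDVI arithmetic, nodata and nearest-neighbour resampling", {
  red <- terra_raster(matrix(0.2, 2, 2), 30)
  nir <- terra_raster(matrix(0.6, 2, 2), 30)
  expect_equal(ndvi(list(red = red, nir = nir))$values, matrix(0.5, 2, 2),
               tolerance = 1e-12)
  expect_true(all(ndvi(list(red = nir, nir = nir))$values == 0))
  z <- terra_raster(matrix(0, 2, 2), 30)
  expect_true(all(is.na(ndvi(list(red = z, nir = z))$values)))
  one <- ndvi(list(red = terra_raster(matrix(0.2, 1, 1), 30),
                   nir = terra_raster(matrix(0.6, 1, 1), 30)),
              target_cell_m = 3)
  expect_equal(dim(one$values), c(10L, 10L))
  expect_equal(unique(as.vector(one$values)), 0.5, tolerance = 1e-12)
})

test_that("standardization centres, scales, and rejects constants", {
  out <- standardize_covariates(tibble::tibble(a = c(1, 2, 3)))
  expect_equal(out$data$a, c(-1, 0, 1))
  expect_equal(unname(out$centers["a"]), 2)
  again <- standardize_covariates(out$data)
  expect_equal(again$data$a, out$data$a, tolerance = 1e-12)
  expect_error(standardize_covariates(tibble::tibble(a = rep(2, 5))), "`a` is constant")
})
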