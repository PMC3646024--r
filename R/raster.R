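#' Georeferenced grid container
#'
#' A minimal north-up raster: a numeric matrix plus grid metadata. Row 1 is
#' the northernmost row; columns run west to east. `origin` is the (x, y)
#' ground coordinate of the *outer* corner of the top-left cell, so the
#' centre of cell `[r, c]` sits at
#' `x = origin_x + (c - 0.5) * cell_size`,
#' `y = origin_y - (r - 0.5) * cell_size`.
#' Missing cells are `NA` internally; `nodata` is only the sentinel used on
#' disk.
#'
#' @param values numeric matrix (rows = north to south).
#' @param cell_size cell edge length in metres (> 0).
#' @param origin length-2 numeric, ground (x, y) of the top-left outer corner.
#' @param nodata numeric sentinel written to / read from ESRI ASCII grids.
#' @param crs_tag free-text coordinate-system tag carried through untouched.
#' @return an object of class `terra_raster`.
#' @export
terra_raster <- function(values, cell_size, origin = c(0, nrow(values) * cell_size),
                         nodata = -9999, crs_tag = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive number.", call. = FALSE)
  }
  if (length(origin) != 2L || any(!is.finite(origin))) {
    stop("`origin` must be a finite (x, y) pair.", call. = FALSE)
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata),
         crs_tag = as.character(crs_tag)),
    class = "terra_raster"
  )
}

#' @export
print.terra_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<terra_raster> %d x %d cells, %.6g m resolution\n",
              nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  origin (top-left corner): (%.6g, %.6g)\n", x$origin[1], x$origin[2]))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (all(is.finite(rng))) {
    cat(sprintf("  values: [%.6g, %.6g], %d NA\n", rng[1], rng[2], sum(is.na(v))))
  } else {
    cat("  values: all NA\n")
  }
  invisible(x)
}

#' @export
dim.terra_raster <- function(x) dim(x$values)

is_raster <- function(x) inherits(x, "terra_raster")

stopifnot_raster <- function(x, arg = "raster") {
  if (!is_raster(x)) stop(sprintf("`%s` must be a terra_raster.", arg), call. = FALSE)
  invisible(x)
}

#' Replace a raster's values, keeping its grid
#' @param r a `terra_raster`.
#' @param values matrix with the same dimensions as `r`.
#' @return a `terra_raster` on the same grid.
#' @export
raster_like <- function(r, values) {
  stopifnot_raster(r)
  values <- as.matrix(values)
  if (!all(dim(values) == dim(r$values))) {
    stop("replacement values have the wrong dimensions.", call. = FALSE)
  }
  terra_raster(values, r$cell_size, r$origin, r$nodata, r$crs_tag)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

#' Ground coordinates of cell centres
#'
#' @param r a `terra_raster`.
#' @return tibble with `row`, `col`, `x`, `y`, `value`.
#' @export
raster_xyz <- function(r) {
  stopifnot_raster(r)
  nr <- nrow(r$values); nc <- ncol(r$values)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = r$origin[1] + (rep(seq_len(nc), each = nr) - 0.5) * r$cell_size,
    y = r$origin[2] - (rep(seq_len(nr), times = nc) - 0.5) * r$cell_size,
    value = as.vector(r$values)
  )
}

#' Row/column of the cell containing ground points
#'
#' Points on a cell boundary belong to the cell to the south/east, matching
#' the half-open cell convention.
#'
#' @param r a `terra_raster`.
#' @param x,y numeric vectors of ground coordinates.
#' @return tibble with `row`, `col` (NA outside the grid).
#' @export
cell_at_xy <- function(r, x, y) {
  stopifnot_raster(r)
  col <- floor((x - r$origin[1]) / r$cell_size) + 1L
  row <- floor((r$origin[2] - y) / r$cell_size) + 1L
  bad <- row < 1L | row > nrow(r$values) | col < 1L | col > ncol(r$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at ground points
#'
#' @inheritParams cell_at_xy
#' @return numeric vector (NA outside the grid).
#' @export
extract_at_xy <- function(r, x, y) {
  rc <- cell_at_xy(r, x, y)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc$row)
  out[ok] <- r$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Read an ESRI ASCII grid
#'
#' Parses the 6-line ASCII grid header (`ncols`, `nrows`, `xllcorner` or
#' `xllcenter`, `yll*`, `cellsize`, `nodata_value`) followed by the value
#' matrix, north row first. Nodata cells become `NA`.
#'
#' @param path file path.
#' @param crs_tag optional coordinate-system tag to attach.
#' @return a `terra_raster`.
#' @export
read_ascii_grid <- function(path, crs_tag = "") {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                    "yllcenter", "cellsize", "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
    if (i > length(lines)) break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid: missing ", paste(setdiff(need, names(hdr)), collapse = ", "),
         call. = FALSE)
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = double(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d.", nr * nc, length(vals)), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  cs <- hdr$cellsize
  xll <- hdr[["xllcorner"]] %||% (hdr[["xllcenter"]] - cs / 2) %||% 0
  yll <- hdr[["yllcorner"]] %||% (hdr[["yllcenter"]] - cs / 2) %||% 0
  terra_raster(m, cs, origin = c(xll, yll + nr * cs), nodata = nodata,
               crs_tag = crs_tag)
}

#' Write an ESRI ASCII grid
#'
#' @param r a `terra_raster`.
#' @param path output file path.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, digits = 8) {
  stopifnot_raster(r)
  nr <- nrow(r$values); nc <- ncol(r$values)
  yll <- r$origin[2] - nr * r$cell_size
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", r$nodata)
  )
  m <- r$values
  m[is.na(m)] <- r$nodata
  body <- apply(m, 1L, function(row) paste(formatC(row, digits = digits, format = "g"),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
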