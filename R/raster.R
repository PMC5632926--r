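#' Create a single-band planar raster grid
#'
#' A `raster_grid` is the carrier for every gridded layer in the package:
#' built-up fraction, land cover, terrain, masks, weighting surfaces and
#' population surfaces. It is a plain numeric (or integer) matrix with a
#' planar geometry: an origin at the lower-left corner, a square cell size in
#' abstract metres, and a nodata sentinel. Row 1 is the top (northernmost)
#' row, matching the on-disk Esri ASCII grid layout.
#'
#' @param values Numeric or integer matrix of cell values.
#' @param origin_x,origin_y Coordinates of the lower-left corner of the grid.
#' @param cell_size Side length of a (square) cell, in abstract metres.
#'   Must be positive.
#' @param nodata Sentinel value marking missing cells. Default -9999.
#'
#' @return An object of class `raster_grid`.
#' @examples
#' r <- raster_grid(matrix(1:6, nrow = 2), cell_size = 100)
#' dim(r$values)
#' @export
raster_grid <- function(values, origin_x = 0, origin_y = 0,
                        cell_size = 100, nodata = -9999) {
  if (!is.matrix(values)) {
    stop("`values` must be a matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      values = values,
      origin_x = origin_x,
      origin_y = origin_y,
      cell_size = cell_size,
      nodata = nodata
    ),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- values_no_nodata(x)
  cat(sprintf(
    "<raster_grid> %d x %d cells, cell_size = %g, origin = (%g, %g)\n",
    nrow(x$values), ncol(x$values), x$cell_size, x$origin_x, x$origin_y
  ))
  if (all(is.na(v))) {
    cat("  all nodata\n")
  } else {
    cat(sprintf(
      "  range [%g, %g], nodata cells: %d\n",
      min(v, na.rm = TRUE), max(v, na.rm = TRUE), sum(is.na(v))
    ))
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

# values with the nodata sentinel replaced by NA
values_no_nodata <- function(grid) {
  v <- grid$values
  v[v == grid$nodata] <- NA
  v
}

#' Cell-centre coordinates of a raster grid
#'
#' @param grid A [raster_grid()].
#' @return A list with matrices `x` and `y` of cell-centre coordinates,
#'   same shape as `grid$values`.
#' @keywords internal
#' @export
raster_xy <- function(grid) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  cs <- grid$cell_size
  x <- matrix(grid$origin_x + (seq_len(nc) - 0.5) * cs,
              nrow = nr, ncol = nc, byrow = TRUE)
  y <- matrix(grid$origin_y + (nr - seq_len(nr) + 0.5) * cs,
              nrow = nr, ncol = nc)
  list(x = x, y = y)
}

#' Check that two raster grids share the same geometry
#'
#' Co-registration means identical shape, origin and cell size; every layer in
#' a covariate stack and every mask must be co-registered before cellwise
#' arithmetic is meaningful.
#'
#' @param a,b [raster_grid()] objects.
#' @param tol Numeric tolerance on origin and cell size comparisons.
#' @return `TRUE` or `FALSE`.
#' @export
is_coregistered <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

stopifnot_coregistered <- function(a, b, what = "rasters") {
  if (!is_coregistered(a, b)) {
    stop(sprintf(
      "%s are not co-registered (shape %dx%d vs %dx%d, cell_size %g vs %g)",
      what, nrow(a$values), ncol(a$values), nrow(b$values), ncol(b$values),
      a$cell_size, b$cell_size
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Nearest-neighbour resampling onto a reference geometry
#'
#' Each target cell takes the value of the source cell containing the target
#' cell's centre. Resampling a grid onto its own geometry is the identity.
#' Target centres falling outside the source extent become nodata.
#'
#' @param grid Source [raster_grid()].
#' @param reference [raster_grid()] supplying the target geometry (its values
#'   are ignored).
#' @return A [raster_grid()] on the reference geometry.
#' @export
resample_nearest <- function(grid, reference) {
  xy <- raster_xy(reference)
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  col <- floor((xy$x - grid$origin_x) / grid$cell_size) + 1L
  row <- nr - floor((xy$y - grid$origin_y) / grid$cell_size)
  inside <- row >= 1L & row <= nr & col >= 1L & col <= nc
  out <- matrix(grid$nodata, nrow(reference$values), ncol(reference$values))
  out[inside] <- grid$values[cbind(row[inside], col[inside])]
  raster_grid(out, reference$origin_x, reference$origin_y,
              reference$cell_size, nodata = grid$nodata)
}

#' Convert a raster grid to a tibble of cell records
#'
#' @param x A [raster_grid()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value` (nodata as
#'   `NA`).
#' @export
#' @exportS3Method tibble::as_tibble
as_tibble.raster_grid <- function(x, ...) {
  xy <- raster_xy(x)
  v <- values_no_nodata(x)
  nr <- nrow(v)
  nc <- ncol(v)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = as.vector(xy$x),
    y = as.vector(xy$y),
    value = as.vector(v)
  )
}

#' Read and write rasters as Esri ASCII grids
#'
#' Plain-text single-band raster interchange: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' rows of values, top row first. Values round-trip exactly for integers and
#' to full double precision for continuous layers (written with 17
#' significant digits).
#'
#' @param path Path to a `.asc` file.
#' @param grid A [raster_grid()] to write.
#' @return `read_raster()` returns a [raster_grid()]; `write_raster()`
#'   returns `path` invisibly.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("raster file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, n = 6L)
  hdr <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) {
    stop(sprintf("not an ASCII grid (bad header): %s", path), call. = FALSE)
  }
  h <- stats::setNames(vals, keys)
  body <- scan(path, skip = 6L, quiet = TRUE)
  if (length(body) != h[["ncols"]] * h[["nrows"]]) {
    stop(sprintf("raster body size mismatch in %s", path), call. = FALSE)
  }
  m <- matrix(body, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  if (all(m == round(m))) storage.mode(m) <- "integer"
  raster_grid(m, h[["xllcorner"]], h[["yllcorner"]], h[["cellsize"]],
              nodata = h[["nodata_value"]])
}

#' @rdname read_raster
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(grid$values)),
    sprintf("nrows %d", nrow(grid$values)),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  ), con)
  fmt <- if (is.integer(grid$values)) "%d" else "%.17g"
  rows <- apply(grid$values, 1L, function(r) paste(sprintf(fmt, r), collapse = " "))
  writeLines(rows, con)
  invisible(path)
}
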