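#' Grid geometry of an aligned raster stack
#'
#' All layers in a landscape share one `grid_spec`. The origin is the
#' lower-left (south-west) corner of the grid; internally row 1 is the
#' southernmost row and the row index increases northward. Each cell covers
#' the half-open square `[edge, edge + cell_size)` in both x and y, so a
#' point lying exactly on a shared edge belongs to the cell whose lower
#' edge it lies on.
#'
#' @param nrows,ncols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in meters (default 300).
#' @param origin_x,origin_y Planar coordinates of the lower-left corner, in
#'   meters.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nrows, ncols, cell_size = 300, origin_x = 0, origin_y = 0) {
  nrows <- as.integer(nrows)
  ncols <- as.integer(ncols)
  if (is.na(nrows) || is.na(ncols) || nrows < 1L || ncols < 1L)
    stop("nrows and ncols must be positive integers")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a positive number")
  structure(
    list(nrows = nrows, ncols = ncols, cell_size = cell_size,
         origin_x = origin_x, origin_y = origin_y),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d rows x %d cols, %g m cells, origin (%g, %g)\n",
              x$nrows, x$ncols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

check_layer_dim <- function(layer, grid, what = "layer") {
  if (!is.matrix(layer) || nrow(layer) != grid$nrows || ncol(layer) != grid$ncols)
    stop(sprintf("%s is not aligned to the grid (%d x %d expected)",
                 what, grid$nrows, grid$ncols))
  invisible(TRUE)
}

# Vectorized point -> (row, col) lookup; NA for points outside the grid.
# Half-open cell rule: floor((coord - origin) / cell_size).
xy_to_rowcol <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((y - grid$origin_y) / grid$cell_size) + 1
  bad <- !is.finite(row) | !is.finite(col) |
    row < 1 | row > grid$nrows | col < 1 | col > grid$ncols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# Values of a matrix layer at planar points; NA outside the grid.
layer_values_at <- function(values, grid, x, y) {
  rc <- xy_to_rowcol(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, 1L])
  if (any(ok)) out[ok] <- values[rc[ok, , drop = FALSE]]
  out
}

# Planar coordinates of cell centers for linear cell indices (column-major).
cell_centers <- function(grid, cells) {
  row <- (cells - 1L) %% grid$nrows + 1L
  col <- (cells - 1L) %/% grid$nrows + 1L
  cbind(x = grid$origin_x + (col - 0.5) * grid$cell_size,
        y = grid$origin_y + (row - 0.5) * grid$cell_size)
}

#' Read a raster layer from an ESRI ASCII grid file
#'
#' Single-band plain-text raster exchange format (`.asc`). The header's
#' `NODATA_value` is honored: matching cells become `NA`. Rows in the file
#' run north to south; they are flipped into the package's internal
#' south-first row order.
#'
#' @param path Path to an ASCII grid file.
#' @return A list with `values` (numeric matrix, row 1 = southernmost row)
#'   and `grid` (a [grid_spec()]).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  header <- list()
  n_header <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    key <- tolower(parts[1L])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      header[[key]] <- as.numeric(parts[2L])
      n_header <- n_header + 1L
    } else break
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(header)))
    stop("not an ESRI ASCII grid: incomplete header in ", path)
  nr <- as.integer(header$nrows)
  nc <- as.integer(header$ncols)
  vals <- scan(path, what = double(), skip = n_header, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d cells, found %d in %s", nr * nc, length(vals), path))
  if (!is.null(header$nodata_value))
    vals[vals == header$nodata_value] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1L, , drop = FALSE]  # file is north-first; internal is south-first
  list(values = m,
       grid = grid_spec(nr, nc, header$cellsize, header$xllcorner, header$yllcorner))
}

#' Write a raster layer as an ESRI ASCII grid file
#'
#' @param values Numeric matrix in internal orientation (row 1 = south).
#' @param grid A [grid_spec()].
#' @param path Output file path.
#' @param nodata Value written for `NA` cells (declared in the header).
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  check_layer_dim(values, grid, "values")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  m <- values[grid$nrows:1L, , drop = FALSE]  # write north-first
  m[is.na(m)] <- nodata
  write.table(format(m, trim = TRUE, digits = 10, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
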