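#' Georeferenced raster grid
#'
#' A `raster_grid` is the common in-memory container for every gridded layer
#' in the package (elevation, land cover, speed, travel time, population).
#' It wraps a numeric matrix (row 1 = northernmost row) together with a
#' geotransform: the coordinates of the lower-left corner, a square cell
#' size in metres, and a CRS identifier. Missing cells are stored as `NA`;
#' the `nodata` sentinel is only used on disk.
#'
#' A projected, metre-based CRS is required. Geographic (degree) CRSs are
#' rejected outright rather than silently reprojected, because cell sizes
#' and travel distances are interpreted in metres throughout.
#'
#' @param values Numeric matrix of cell values, row 1 at the top (north).
#' @param origin_x,origin_y Coordinates (metres) of the lower-left corner
#'   of the grid extent.
#' @param cell_size Cell edge length in metres (> 0, square cells).
#' @param crs CRS identifier string (e.g. `"EPSG:32644"` for WGS84/UTM 44N).
#' @param nodata Sentinel written for `NA` cells on disk. Use `255` for
#'   categorical layers, `-9999` (default) for continuous ones.
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:6, nrow = 2), 0, 0, 30)
#' dim(g$values)
#' @export
raster_grid <- function(values, origin_x, origin_y, cell_size,
                        crs = "EPSG:32644", nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cell_size), length(cell_size) == 1, cell_size > 0)
  stopifnot(nrow(values) >= 1, ncol(values) >= 1)
  assert_projected_crs(crs)
  bad <- is.infinite(values)
  if (any(bad, na.rm = TRUE)) {
    stop("raster values must be finite or NA", call. = FALSE)
  }
  structure(
    list(
      values = values,
      origin_x = as.numeric(origin_x),
      origin_y = as.numeric(origin_y),
      cell_size = as.numeric(cell_size),
      crs = crs,
      nodata = as.numeric(nodata)
    ),
    class = "raster_grid"
  )
}

assert_projected_crs <- function(crs) {
  if (is.null(crs) || is.na(crs)) return(invisible(TRUE))
  if (grepl("4326|longlat|degree|CRS84", crs, ignore.case = TRUE)) {
    stop(
      "geographic (degree) CRS '", crs, "' is not supported; ",
      "supply data in a projected metric CRS (e.g. a UTM zone)",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(
    "<raster_grid> ", nrow(v), " x ", ncol(v),
    " cells @ ", x$cell_size, " m  [", x$crs, "]\n",
    sep = ""
  )
  ext <- grid_extent(x)
  cat(sprintf(
    "  extent: x %.1f..%.1f  y %.1f..%.1f\n",
    ext["xmin"], ext["xmax"], ext["ymin"], ext["ymax"]
  ))
  fin <- v[!is.na(v)]
  if (length(fin)) {
    cat(sprintf(
      "  values: %.6g .. %.6g  (%d NA)\n",
      min(fin), max(fin), sum(is.na(v))
    ))
  } else {
    cat("  values: all NA\n")
  }
  invisible(x)
}

#' Grid extent
#'
#' @param grid A [raster_grid()].
#' @return Named numeric vector `xmin, xmax, ymin, ymax` (metres).
#' @export
grid_extent <- function(grid) {
  c(
    xmin = grid$origin_x,
    xmax = grid$origin_x + ncol(grid$values) * grid$cell_size,
    ymin = grid$origin_y,
    ymax = grid$origin_y + nrow(grid$values) * grid$cell_size
  )
}

same_frame <- function(a, b, tol = 1e-6) {
  isTRUE(
    nrow(a$values) == nrow(b$values) &&
      ncol(a$values) == ncol(b$values) &&
      abs(a$origin_x - b$origin_x) < tol &&
      abs(a$origin_y - b$origin_y) < tol &&
      abs(a$cell_size - b$cell_size) < tol
  )
}

assert_same_frame <- function(..., what = "rasters") {
  grids <- list(...)
  for (i in seq_along(grids)[-1]) {
    if (!same_frame(grids[[1]], grids[[i]])) {
      stop(what, " are not on the same reference frame", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# cell centres for (row, col) index vectors
cell_centre_xy <- function(grid, row, col) {
  cs <- grid$cell_size
  ymax <- grid$origin_y + nrow(grid$values) * cs
  list(
    x = grid$origin_x + (col - 0.5) * cs,
    y = ymax - (row - 0.5) * cs
  )
}

# (row, col) of the cell containing each (x, y); points on the top/right
# boundary fall into the last cell. Returns NA outside the extent.
xy_to_cell <- function(grid, x, y) {
  cs <- grid$cell_size
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  ymax <- grid$origin_y + nr * cs
  col <- floor((x - grid$origin_x) / cs) + 1L
  row <- floor((ymax - y) / cs) + 1L
  col[x == grid$origin_x + nc * cs] <- nc
  row[y == grid$origin_y] <- nr
  out <- col < 1L | col > nc | row < 1L | row > nr
  col[out] <- NA_integer_
  row[out] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Convert a raster grid to a tibble
#'
#' One row per cell, with row/column indices, cell-centre coordinates and
#' the value; handy for piping into ggplot2 or dplyr.
#'
#' @param x A [raster_grid()].
#' @param ... Unused.
#' @param drop_na Drop `NA` cells (default `FALSE`).
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @method as_tibble raster_grid
#' @export
as_tibble.raster_grid <- function(x, ..., drop_na = FALSE) {
  nr <- nrow(x$values)
  nc <- ncol(x$values)
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  ctr <- cell_centre_xy(x, row, col)
  val <- as.vector(x$values)
  out <- tibble::tibble(
    row = row, col = col, x = ctr$x, y = ctr$y, value = val
  )
  if (drop_na) out <- dplyr::filter(out, !is.na(.data$value))
  out
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
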