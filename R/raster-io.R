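#' Read a raster from an ESRI ASCII grid file
#'
#' Reads a single-band `.asc` raster (the plain-text ESRI ASCII grid
#' interchange format) into a [raster_grid()]. If a `.prj` sidecar exists
#' next to the file its contents are used as the CRS identifier.
#'
#' Cells equal to the file's `NODATA_value` become `NA`. Only square cells
#' are supported; files carrying separate `dx`/`dy` headers are rejected.
#'
#' @param path Path to a `.asc` file.
#' @param crs CRS to assume when no `.prj` sidecar is present.
#' @return A [raster_grid()].
#' @seealso [write_raster()]
#' @export
read_raster <- function(path, crs = "EPSG:32644") {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 7L, warn = FALSE)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else {
      break
    }
  }
  if (any(c("dx", "dy") %in% names(hdr))) {
    stop("non-square cells (dx/dy headers) are not supported: ", path,
         call. = FALSE)
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not a valid ESRI ASCII grid (missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "), "): ", path,
         call. = FALSE)
  }
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if ("xllcorner" %in% names(hdr)) {
    ox <- hdr$xllcorner
    oy <- hdr$yllcorner
  } else if ("xllcenter" %in% names(hdr)) {
    ox <- hdr$xllcenter - cs / 2
    oy <- hdr$yllcenter - cs / 2
  } else {
    stop("ASCII grid header lacks an origin (xllcorner/xllcenter): ", path,
         call. = FALSE)
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("expected ", nr * nc, " cell values, found ", length(vals),
         " in ", path, call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  prj <- sub("\\.asc$", ".prj", path)
  if (file.exists(prj)) {
    crs <- trimws(paste(readLines(prj, warn = FALSE), collapse = " "))
  }
  raster_grid(m, ox, oy, cs, crs = crs, nodata = nodata)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Values are written at full double precision (17 significant digits) so
#' `read_raster(write_raster(g))` round-trips bit-identically, including
#' the `NA` mask (written as the grid's `nodata` sentinel) and the
#' geotransform. A `.prj` sidecar carrying the CRS string is written
#' alongside.
#'
#' @param grid A [raster_grid()].
#' @param path Output path (`.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("cannot write raster: directory does not exist: ", dir, call. = FALSE)
  }
  v <- grid$values
  if (any(v == grid$nodata, na.rm = TRUE)) {
    stop("raster contains cells equal to its nodata sentinel (",
         grid$nodata, "); choose a different sentinel", call. = FALSE)
  }
  v[is.na(v)] <- grid$nodata
  hdr <- c(
    paste("ncols", ncol(grid$values)),
    paste("nrows", nrow(grid$values)),
    paste("xllcorner", format(grid$origin_x, digits = 17)),
    paste("yllcorner", format(grid$origin_y, digits = 17)),
    paste("cellsize", format(grid$cell_size, digits = 17)),
    paste("NODATA_value", format(grid$nodata, digits = 17))
  )
  body <- apply(v, 1, function(r) paste(format(r, digits = 17), collapse = " "))
  writeLines(c(hdr, body), path)
  if (!is.null(grid$crs) && !is.na(grid$crs)) {
    writeLines(grid$crs, sub("\\.asc$", ".prj", path))
  }
  invisible(path)
}

#' Read line features from a GeoJSON file
#'
#' Supports `LineString` and `MultiLineString` geometries in a
#' `FeatureCollection`. Feature properties become tibble columns; the
#' geometry becomes a list-column of two-column coordinate matrices (one
#' matrix per part).
#'
#' @param path Path to a GeoJSON file.
#' @return A tibble with one row per line part: `feature_id`, `part`, any
#'   property columns, and a `geometry` list-column of `n x 2` matrices.
#' @export
read_lines_geojson <- function(path) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  rows <- purrr::imap(gj$features, function(feat, i) {
    geom <- feat$geometry
    parts <- switch(
      geom$type,
      LineString = list(geom$coordinates),
      MultiLineString = geom$coordinates,
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    props <- feat$properties %||% list()
    purrr::imap(parts, function(coords, j) {
      m <- do.call(rbind, purrr::map(coords, ~ as.numeric(.x[1:2])))
      tibble::tibble(
        feature_id = i, part = j,
        !!!purrr::map(props, ~ if (is.null(.x)) NA else .x),
        geometry = list(m)
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Write line features to a GeoJSON file
#'
#' Inverse of [read_lines_geojson()]: each row becomes one `LineString`
#' feature whose properties are the non-geometry columns.
#'
#' @param lines Tibble with a `geometry` list-column of `n x 2` matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lines_geojson <- function(lines, path) {
  stopifnot("geometry" %in% names(lines))
  prop_cols <- setdiff(names(lines), c("geometry", "feature_id", "part"))
  features <- purrr::map(seq_len(nrow(lines)), function(i) {
    coords <- lines$geometry[[i]]
    props <- purrr::map(
      stats::setNames(prop_cols, prop_cols),
      ~ lines[[.x]][[i]]
    )
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "LineString",
        coordinates = purrr::map(seq_len(nrow(coords)),
                                 ~ c(coords[.x, 1], coords[.x, 2]))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
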