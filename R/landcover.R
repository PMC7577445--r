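#' The merged land-cover legend
#'
#' The analysis runs on a single categorical grid combining seven generic
#' land-cover classes with rasterized roads (three tiers, the tertiary
#' tier split by passability) and impassable water barriers — twelve
#' classes in all. Lower road codes are faster road tiers.
#'
#' @return A tibble with columns `code` (1-12), `label`, and `group`
#'   (`"landcover"`, `"barrier"` or `"road"`).
#' @export
merged_classes <- function() {
  tibble::tibble(
    code = 1:12,
    label = c(
      "Forestland", "Grassland/Plantation", "Cropland", "Settlement",
      "Wasteland/Fallow/Other", "Waterbodies", "Snowcapped",
      "MajorRoad", "SecondaryRoad", "TertiaryAllVehicle",
      "TertiaryTwoWheeler", "TertiaryWalkOnly"
    ),
    group = c(rep("landcover", 5), "barrier", "landcover", rep("road", 5))
  )
}

#' Barrier class codes
#'
#' Cells in these classes are impassable to every travel mode and act as
#' physical barriers (population on them is redistributed, facilities are
#' snapped off them).
#' @return Integer vector of merged-class codes.
#' @export
barrier_codes <- function() {
  mc <- merged_classes()
  mc$code[mc$group == "barrier"]
}

#' Reclassify a raw land-cover raster into generic classes
#'
#' Collapses a many-class source land-cover product (e.g. an 18-class
#' national map) into the seven generic classes of the merged legend. The
#' mapping is user input: which source classes belong to which generic
#' class depends on the product's own legend.
#'
#' @param raw Categorical [raster_grid()] of source class codes.
#' @param table Data frame with columns `raw_code` and either `code`
#'   (merged code) or `label` (merged label).
#' @return A categorical [raster_grid()] on the same frame; `NA` preserved.
#' @export
reclassify_landcover <- function(raw, table) {
  stopifnot(inherits(raw, "raster_grid"), "raw_code" %in% names(table))
  if (!"code" %in% names(table)) {
    stopifnot("label" %in% names(table))
    table$code <- merged_classes()$code[
      match(table$label, merged_classes()$label)
    ]
    if (anyNA(table$code)) {
      stop("unknown merged-class labels: ",
           paste(unique(table$label[is.na(table$code)]), collapse = ", "),
           call. = FALSE)
    }
  }
  vals <- raw$values
  present <- unique(vals[!is.na(vals)])
  unmapped <- setdiff(present, table$raw_code)
  if (length(unmapped)) {
    stop("raw land-cover codes with no reclass entry: ",
         paste(sort(unmapped), collapse = ", "), call. = FALSE)
  }
  out <- matrix(
    table$code[match(as.vector(vals), table$raw_code)],
    nrow = nrow(vals)
  )
  raster_grid(out, raw$origin_x, raw$origin_y, raw$cell_size,
              crs = raw$crs, nodata = 255)
}

# All cells a segment passes through, by Amanatides-Woo grid traversal
# (all-touched; a tie at a cell corner steps diagonally). Returns a
# two-column matrix (row, col), possibly with out-of-bounds indices.
trace_cells <- function(grid, x0, y0, x1, y1) {
  cs <- grid$cell_size
  nr <- nrow(grid$values)
  ymax <- grid$origin_y + nr * cs
  gx0 <- (x0 - grid$origin_x) / cs; gy0 <- (ymax - y0) / cs
  gx1 <- (x1 - grid$origin_x) / cs; gy1 <- (ymax - y1) / cs
  cx <- floor(gx0); cy <- floor(gy0)
  ex <- floor(gx1); ey <- floor(gy1)
  dx <- gx1 - gx0; dy <- gy1 - gy0
  step_x <- sign(dx); step_y <- sign(dy)
  tmax_x <- if (dx > 0) (cx + 1 - gx0) / dx else if (dx < 0) (gx0 - cx) / -dx else Inf
  tmax_y <- if (dy > 0) (cy + 1 - gy0) / dy else if (dy < 0) (gy0 - cy) / -dy else Inf
  tdx <- if (dx != 0) abs(1 / dx) else Inf
  tdy <- if (dy != 0) abs(1 / dy) else Inf
  max_iter <- 2L * (abs(ex - cx) + abs(ey - cy)) + 4L
  cells <- matrix(0L, nrow = max_iter + 1L, ncol = 2)
  n <- 1L
  cells[1, ] <- c(cy + 1L, cx + 1L)
  it <- 0L
  while ((cx != ex || cy != ey) && it < max_iter) {
    it <- it + 1L
    if (abs(tmax_x - tmax_y) < 1e-12) {
      cx <- cx + step_x; cy <- cy + step_y
      tmax_x <- tmax_x + tdx; tmax_y <- tmax_y + tdy
    } else if (tmax_x < tmax_y) {
      cx <- cx + step_x; tmax_x <- tmax_x + tdx
    } else {
      cy <- cy + step_y; tmax_y <- tmax_y + tdy
    }
    n <- n + 1L
    cells[n, ] <- c(cy + 1L, cx + 1L)
  }
  cells[seq_len(n), , drop = FALSE]
}

#' Rasterize line features onto a reference frame
#'
#' Burns each line's class code into every cell the line passes through
#' ("all touched" intersection, which preserves network connectivity at
#' coarse resolutions where centre-sampling breaks it). Where lines of
#' different classes cross in one cell, the smallest code wins — in the
#' merged legend smaller road codes are higher (faster) tiers.
#'
#' @param lines Tibble with a `geometry` list-column of `n x 2` coordinate
#'   matrices (as from [read_lines_geojson()]); may be empty.
#' @param reference A [raster_grid()] giving the target frame.
#' @param class_attr Name of the column holding each line's class code.
#' @return Categorical [raster_grid()]; untouched cells are `NA`.
#' @export
rasterize_lines <- function(lines, reference, class_attr = "code") {
  stopifnot(inherits(reference, "raster_grid"))
  nr <- nrow(reference$values)
  nc <- ncol(reference$values)
  out <- matrix(NA_real_, nr, nc)
  if (nrow(lines) > 0) {
    stopifnot(class_attr %in% names(lines))
    ord <- order(lines[[class_attr]], decreasing = TRUE)
    for (i in ord) {
      coords <- lines$geometry[[i]]
      code <- lines[[class_attr]][[i]]
      for (s in seq_len(nrow(coords) - 1L)) {
        cells <- trace_cells(
          reference,
          coords[s, 1], coords[s, 2], coords[s + 1L, 1], coords[s + 1L, 2]
        )
        keep <- cells[, 1] >= 1L & cells[, 1] <= nr &
          cells[, 2] >= 1L & cells[, 2] <= nc
        cells <- cells[keep, , drop = FALSE]
        if (nrow(cells)) {
          prev <- out[cells]
          out[cells] <- pmin(prev, code, na.rm = TRUE)
        }
      }
    }
  }
  raster_grid(out, reference$origin_x, reference$origin_y,
              reference$cell_size, crs = reference$crs, nodata = 255)
}

#' Stack generic land cover, roads and barriers into the merged grid
#'
#' Per cell the priority is barrier > road > generic land cover: water is
#' impassable to every mode, so a road segment crossing a water cell is
#' clipped (the cell stays water).
#'
#' @param generic Categorical [raster_grid()] of the 7 generic classes.
#' @param roads Categorical [raster_grid()] of road codes (`NA` = no road).
#' @param barriers [raster_grid()] whose non-`NA` cells are barriers.
#' @return Categorical [raster_grid()] with at most 12 classes.
#' @export
merge_layers <- function(generic, roads, barriers) {
  assert_same_frame(generic, roads, barriers)
  out <- generic$values
  r <- roads$values
  out[!is.na(r)] <- r[!is.na(r)]
  water <- barrier_codes()[1]
  out[!is.na(barriers$values)] <- water
  raster_grid(out, generic$origin_x, generic$origin_y, generic$cell_size,
              crs = generic$crs, nodata = 255)
}

#' Move points off barrier cells
#'
#' A facility digitised onto a water cell cannot seed a travel-time
#' surface; it is relocated to the centre of the nearest non-barrier cell
#' (Euclidean cell-centre distance; ties broken by lowest row, then
#' column, for determinism). Points already on traversable cells are
#' returned unchanged.
#'
#' @param points Tibble with `x` and `y` columns (metres, same CRS as the
#'   grid).
#' @param merged The merged land-cover [raster_grid()].
#' @param barriers Barrier class codes (default [barrier_codes()]).
#' @return `points` with `x`, `y` updated and a logical `snapped` column.
#' @export
snap_points_off_barriers <- function(points, merged, barriers = barrier_codes()) {
  stopifnot(all(c("x", "y") %in% names(points)))
  land <- which(!(merged$values %in% barriers) & !is.na(merged$values),
                arr.ind = TRUE)
  if (nrow(land) == 0) stop("no non-barrier cell exists", call. = FALSE)
  land_xy <- cell_centre_xy(merged, land[, 1], land[, 2])
  idx <- xy_to_cell(merged, points$x, points$y)
  on_barrier <- !is.na(idx$row) &
    merged$values[cbind(idx$row, idx$col)] %in% barriers
  points$snapped <- on_barrier
  for (i in which(on_barrier)) {
    d2 <- (land_xy$x - points$x[i])^2 + (land_xy$y - points$y[i])^2
    best <- order(d2, land[, 1], land[, 2])[1]
    points$x[i] <- land_xy$x[best]
    points$y[i] <- land_xy$y[best]
  }
  points
}
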