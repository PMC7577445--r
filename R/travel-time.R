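#' Anisotropic least-cost travel time toward facilities
#'
#' Computes, for every traversable cell, the minimum travel time (hours)
#' a patient needs to reach the nearest of the supplied facilities,
#' moving over the 8-connected cell graph of a friction (speed) surface.
#'
#' The directed cost of moving from cell `a` to neighbouring cell `b` is
#' split half-and-half between the two cells:
#' `cost(a -> b) = (d/2) / v_a + (d/2) / v_b`, with `d` the centre-to-centre
#' distance (`cell_size`, or `cell_size * sqrt(2)` diagonally). On walking
#' cells the speed is slope-corrected with [tobler_speed()] using the
#' gradient experienced in the direction of motion,
#' `S = (elev(b) - elev(a)) / d`; motorized cells use the flat speed. The
#' surface is therefore anisotropic: it is the time *toward* the facility,
#' not from it. Facility cells have time 0; barriers and cells with no
#' path to any facility are `NA`.
#'
#' The shortest-path solve runs a multi-source Dijkstra (via igraph) over
#' the reversed directed graph, so each path is costed in the patient's
#' direction of travel.
#'
#' @param facilities Tibble of facility points with `x`, `y` (and
#'   optionally `facility_id`) — pre-filtered to the facilities providing
#'   the service of interest.
#' @param speed Flat-speed [raster_grid()] (km/h, `NA` = impassable), as
#'   from [build_speed_surface()].
#' @param walking_mask 1/0 [raster_grid()] marking walking-mode cells.
#' @param dem Elevation [raster_grid()] (metres), co-registered.
#' @param scenario_name,service Labels stored on the result.
#' @return A `travel_surface`: list with `time` ([raster_grid()], hours),
#'   `scenario_name`, `service`.
#' @export
travel_time_toward <- function(facilities, speed, walking_mask, dem,
                               scenario_name = "", service = "") {
  assert_same_frame(speed, walking_mask, dem)
  if (any(speed$values <= 0, na.rm = TRUE)) {
    stop("speed surface contains non-positive speeds", call. = FALSE)
  }
  trav <- !is.na(speed$values)
  src <- facility_vertices(facilities, speed, trav)
  edges <- grid_edges(speed, walking_mask, dem, trav)
  d <- dijkstra_to_sources(edges, sum(trav), src$vid)
  time <- matrix(NA_real_, nrow(speed$values), ncol(speed$values))
  time[trav] <- d
  time[is.infinite(time)] <- NA_real_
  new_travel_surface(
    raster_grid(time, speed$origin_x, speed$origin_y, speed$cell_size,
                crs = speed$crs, nodata = -9999),
    scenario_name, service
  )
}

new_travel_surface <- function(time, scenario_name, service) {
  structure(
    list(time = time, scenario_name = scenario_name, service = service),
    class = "travel_surface"
  )
}

#' @export
print.travel_surface <- function(x, ...) {
  cat("<travel_surface> scenario: ", x$scenario_name,
      "  service: ", x$service, "\n", sep = "")
  print(x$time)
  invisible(x)
}

# map facility coordinates to traversable-cell vertex ids
facility_vertices <- function(facilities, speed, trav) {
  stopifnot(all(c("x", "y") %in% names(facilities)), nrow(facilities) >= 1)
  idx <- xy_to_cell(speed, facilities$x, facilities$y)
  if (anyNA(idx$row)) {
    stop("facilities outside the raster extent", call. = FALSE)
  }
  cell <- cbind(idx$row, idx$col)
  on_trav <- trav[cell]
  if (!any(on_trav)) {
    stop("no facility lies on a traversable cell; ",
         "snap facilities off barriers first", call. = FALSE)
  }
  vid_map <- matrix(NA_integer_, nrow(trav), ncol(trav))
  vid_map[trav] <- seq_len(sum(trav))
  list(vid = unique(vid_map[cell[on_trav, , drop = FALSE]]), cell = cell)
}

# Directed edge table over the 8-connected traversable-cell graph.
# Columns: from, to (vertex ids among traversable cells), w (hours).
grid_edges <- function(speed, walking_mask, dem, trav = !is.na(speed$values)) {
  nr <- nrow(speed$values)
  nc <- ncol(speed$values)
  cs_km <- speed$cell_size / 1000
  vid <- matrix(NA_integer_, nr, nc)
  vid[trav] <- seq_len(sum(trav))

  sp <- speed$values
  wk <- walking_mask$values
  el <- dem$values

  froms <- tos <- ws <- vector("list", 8)
  k <- 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r_lo <- max(1, 1 - dr); r_hi <- min(nr, nr - dr)
    c_lo <- max(1, 1 - dc); c_hi <- min(nc, nc - dc)
    if (r_lo > r_hi || c_lo > c_hi) next
    f_idx <- as.matrix(expand.grid(row = r_lo:r_hi, col = c_lo:c_hi))
    t_idx <- cbind(f_idx[, 1] + dr, f_idx[, 2] + dc)
    ok <- trav[f_idx] & trav[t_idx]
    if (!any(ok)) next
    f_idx <- f_idx[ok, , drop = FALSE]
    t_idx <- t_idx[ok, , drop = FALSE]
    d_km <- cs_km * sqrt(dr^2 + dc^2)
    d_m <- d_km * 1000
    s <- (el[t_idx] - el[f_idx]) / d_m
    v_from <- sp[f_idx]
    v_to <- sp[t_idx]
    wf <- wk[f_idx] == 1
    wt <- wk[t_idx] == 1
    v_from[wf] <- tobler_speed(v_from[wf], s[wf])
    v_to[wt] <- tobler_speed(v_to[wt], s[wt])
    k <- k + 1
    froms[[k]] <- vid[f_idx]
    tos[[k]] <- vid[t_idx]
    ws[[k]] <- (d_km / 2) / v_from + (d_km / 2) / v_to
  }
  list(
    from = unlist(froms), to = unlist(tos), w = unlist(ws)
  )
}

# shortest directed-path cost from every vertex to the nearest source,
# following edge direction (from -> to); returns a vector over vertices
dijkstra_to_sources <- function(edges, n_vertices, source_vids) {
  sink <- n_vertices + 1L
  ef <- c(edges$from, source_vids)
  et <- c(edges$to, rep(sink, length(source_vids)))
  ew <- c(edges$w, rep(0, length(source_vids)))
  g <- igraph::make_empty_graph(n = sink, directed = TRUE)
  g <- igraph::add_edges(g, rbind(ef, et), weight = ew)
  d <- igraph::distances(g, v = sink, to = seq_len(n_vertices),
                         mode = "in", algorithm = "dijkstra")
  as.numeric(d[1, ])
}

#' Classify a travel-time surface into incremental zones
#'
#' Four incremental travel-time zones with closed upper bounds:
#' `(0,1]`, `(1,2]`, `(2,3]` and `(3, Inf)` hours, coded 1-4. `NA`
#' (barrier/unreachable) propagates.
#'
#' @param surface A `travel_surface` (or a time [raster_grid()]).
#' @return Categorical [raster_grid()] with codes 1-4 and a
#'   `zone_labels` attribute.
#' @export
classify_time_zones <- function(surface) {
  time <- if (inherits(surface, "travel_surface")) surface$time else surface
  z <- matrix(
    as.numeric(cut(as.vector(time$values), breaks = c(-Inf, 1, 2, 3, Inf),
                   right = TRUE, labels = FALSE)),
    nrow = nrow(time$values)
  )
  out <- raster_grid(z, time$origin_x, time$origin_y, time$cell_size,
                     crs = time$crs, nodata = 255)
  attr(out, "zone_labels") <- time_zone_labels()
  out
}

#' @rdname classify_time_zones
#' @export
time_zone_labels <- function() {
  c("<=1h", "1-2h", "2-3h", ">3h")
}

#' Sample a travel-time surface at village centroids
#'
#' Looks up each village's travel time, assigns its incremental zone, and
#' summarizes: the share of villages per time zone and the median travel
#' time. Villages on `NA` cells (barriers, disconnected areas) are
#' flagged unreachable; they are reported separately and excluded from
#' the zone shares and the median.
#'
#' @param villages Tibble with `village_id`, `x`, `y` (and any other
#'   columns, which are carried through).
#' @param surface A `travel_surface`.
#' @return List with `villages` (input + `time_h`, `time_zone`,
#'   `unreachable`), `zone_shares` (tibble `time_zone`, `n`,
#'   `pct_villages` over reachable villages), `median_time_h`, and
#'   `n_unreachable`.
#' @export
village_travel_summary <- function(villages, surface) {
  stopifnot(all(c("x", "y") %in% names(villages)))
  time <- surface$time
  idx <- xy_to_cell(time, villages$x, villages$y)
  if (anyNA(idx$row)) {
    stop("villages outside the raster extent: ",
         paste(which(is.na(idx$row)), collapse = ", "), call. = FALSE)
  }
  t_h <- time$values[cbind(idx$row, idx$col)]
  labs <- time_zone_labels()
  out <- dplyr::mutate(
    villages,
    time_h = t_h,
    time_zone = labs[cut(t_h, c(-Inf, 1, 2, 3, Inf), labels = FALSE)],
    unreachable = is.na(t_h)
  )
  reach <- dplyr::filter(out, !.data$unreachable)
  shares <- tibble::tibble(time_zone = factor(labs, levels = labs)) |>
    dplyr::left_join(
      dplyr::count(reach, time_zone = factor(.data$time_zone, levels = labs)),
      by = "time_zone"
    ) |>
    tidyr::replace_na(list(n = 0L)) |>
    dplyr::mutate(
      pct_villages = if (nrow(reach)) 100 * .data$n / nrow(reach) else NA_real_
    )
  list(
    villages = out,
    zone_shares = shares,
    median_time_h = stats::median(reach$time_h),
    n_unreachable = sum(out$unreachable)
  )
}
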