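#' Facility population-coverage capacity
#'
#' The maximum number of people a facility can cover per year.
#'
#' For outpatient-oriented facilities (sub-centres, primary health
#' centres) the capacity is
#' `workers * patients_per_worker_day * working_days / visits_per_capita`.
#' For bed-based facilities (community health centres, district
#' hospitals) it is
#' `beds * occupancy * working_days / (admittances_per_capita * alos)`.
#' All arguments are vectorised.
#'
#' @param n_health_workers Number of health workers.
#' @param patients_per_worker_day Patients one worker sees per average day.
#' @param working_days_per_year Working days per year.
#' @param outpatient_visits_per_capita_year Average outpatient visits per
#'   person per year (> 0).
#' @return Capacity in persons.
#' @examples
#' outpatient_capacity(3, 20, 300, 2) # 9000
#' inpatient_capacity(30, 0.8, 365, 0.05, 5) # 35040
#' @export
outpatient_capacity <- function(n_health_workers, patients_per_worker_day,
                                working_days_per_year,
                                outpatient_visits_per_capita_year) {
  if (any(outpatient_visits_per_capita_year <= 0, na.rm = TRUE)) {
    stop("outpatient visits per capita must be > 0", call. = FALSE)
  }
  (n_health_workers * patients_per_worker_day * working_days_per_year) /
    outpatient_visits_per_capita_year
}

#' @rdname outpatient_capacity
#' @param n_beds Number of beds.
#' @param occupancy_rate Bed occupancy rate in (0, 1].
#' @param admittances_per_capita_year Average inpatient admittances per
#'   person per year (> 0).
#' @param average_length_of_stay Average stay in days (> 0).
#' @export
inpatient_capacity <- function(n_beds, occupancy_rate, working_days_per_year,
                               admittances_per_capita_year,
                               average_length_of_stay) {
  if (any(admittances_per_capita_year <= 0, na.rm = TRUE) ||
      any(average_length_of_stay <= 0, na.rm = TRUE)) {
    stop("admittances per capita and length of stay must be > 0",
         call. = FALSE)
  }
  if (any(occupancy_rate == 0, na.rm = TRUE)) {
    warning("occupancy rate of 0 gives a degenerate zero capacity")
  }
  (n_beds * occupancy_rate * working_days_per_year) /
    (admittances_per_capita_year * average_length_of_stay)
}

#' Derive coverage capacity for a facility table
#'
#' Applies the outpatient formula to `SC`/`PHC` rows and the bed-based
#' formula to `CHC`/`DH` rows, adding a `capacity` column.
#'
#' @param facilities Tibble with `tier` and the capacity-input columns
#'   `workers`, `patients_per_day`, `working_days`, `visits_per_capita`
#'   (outpatient tiers) and `beds`, `occupancy`, `admittances_per_capita`,
#'   `alos` (bed-based tiers); unused fields may be `NA`.
#' @return `facilities` with a `capacity` column (persons).
#' @export
facility_capacities <- function(facilities) {
  stopifnot("tier" %in% names(facilities))
  outp <- facilities$tier %in% c("SC", "PHC")
  cap <- numeric(nrow(facilities))
  cap[outp] <- outpatient_capacity(
    facilities$workers[outp], facilities$patients_per_day[outp],
    facilities$working_days[outp], facilities$visits_per_capita[outp]
  )
  cap[!outp] <- inpatient_capacity(
    facilities$beds[!outp], facilities$occupancy[!outp],
    facilities$working_days[!outp],
    facilities$admittances_per_capita[!outp], facilities$alos[!outp]
  )
  dplyr::mutate(facilities, capacity = cap)
}

#' Redistribute population off barrier cells
#'
#' Gridded population products routinely place people on cells that the
#' merged land cover marks as water. Each barrier cell's population is
#' moved to its nearest non-barrier cell (Euclidean cell-centre distance,
#' ties broken by lowest row then column); the total is conserved
#' exactly and barrier cells end at 0.
#'
#' @param population Population [raster_grid()] (persons per cell).
#' @param merged Merged land-cover [raster_grid()], co-registered.
#' @param barriers Barrier codes (default [barrier_codes()]).
#' @return Corrected population [raster_grid()].
#' @export
correct_population_off_barriers <- function(population, merged,
                                            barriers = barrier_codes()) {
  assert_same_frame(population, merged)
  pop <- population$values
  is_barrier <- merged$values %in% barriers
  src <- which(is_barrier & !is.na(pop) & pop > 0, arr.ind = TRUE)
  if (nrow(src)) {
    land <- which(!is_barrier & !is.na(merged$values), arr.ind = TRUE)
    if (nrow(land) == 0) stop("no non-barrier cell exists", call. = FALSE)
    land_xy <- cell_centre_xy(population, land[, 1], land[, 2])
    src_xy <- cell_centre_xy(population, src[, 1], src[, 2])
    for (i in seq_len(nrow(src))) {
      d2 <- (land_xy$x - src_xy$x[i])^2 + (land_xy$y - src_xy$y[i])^2
      best <- order(d2, land[, 1], land[, 2])[1]
      tgt <- land[best, , drop = FALSE]
      moved <- pop[src[i, 1], src[i, 2]]
      if (is.na(pop[tgt])) pop[tgt] <- 0
      pop[tgt] <- pop[tgt] + moved
    }
  }
  pop[is_barrier] <- 0
  raster_grid(pop, population$origin_x, population$origin_y,
              population$cell_size, crs = population$crs,
              nodata = population$nodata)
}

#' Delineate capacity-constrained facility catchments
#'
#' Grows an exclusive catchment around each facility, jointly bounded by
#' a maximum travel time and the facility's coverage capacity. Facilities
#' are processed sequentially in descending capacity (ties broken by
#' facility id). For each facility its anisotropic travel-time surface is
#' computed over the full landscape; the cells no facility has yet
#' claimed are then claimed in ascending travel-time order (ties by row,
#' column), accumulating their population, until either the unclaimed
#' reachable cells within `max_time` are exhausted
#' (`stop_reason = "max_travel_time"`) or adding the next cell would
#' exceed the capacity (`stop_reason = "max_capacity"`). Cells are
#' claimed whole: a cell that would overflow the capacity is left to
#' other facilities, so served population never exceeds capacity. Earlier
#' catchments do not block travel for later facilities (patients may
#' traverse another catchment), so with unlimited capacities the result
#' reduces exactly to pure accessibility within `max_time`.
#'
#' @param facilities Tibble with `facility_id`, `x`, `y`, `capacity`
#'   (pre-filtered to the service of interest and with coordinates
#'   already snapped off barriers).
#' @param merged Merged land-cover [raster_grid()].
#' @param dem Elevation [raster_grid()].
#' @param population Barrier-corrected population [raster_grid()].
#' @param scenario Scenario tibble (see [scenario_table()]).
#' @param max_time Maximum travel time in hours (> 0); 1 h is typical for
#'   ambulatory/immunization care, 2 h for delivery and inpatient care.
#' @return A `catchment_set`: list with `results` (per-facility tibble:
#'   `facility_id`, `capacity`, `served_population`, `n_cells`,
#'   `stop_reason`, `max_time_used`), `catchments` (facility-index
#'   [raster_grid()]), `served` and `unserved` population rasters,
#'   `max_time`, `scenario_name`.
#' @export
delineate_catchments <- function(facilities, merged, dem, population,
                                 scenario, max_time) {
  stopifnot(nrow(facilities) > 0, max_time > 0)
  stopifnot(all(c("facility_id", "x", "y", "capacity") %in% names(facilities)))
  assert_same_frame(merged, dem, population)
  sf <- build_speed_surface(merged, scenario)
  trav0 <- !is.na(sf$speed$values)
  edges <- grid_edges(sf$speed, sf$walking_mask, dem, trav0)
  vid <- matrix(NA_integer_, nrow(trav0), ncol(trav0))
  vid[trav0] <- seq_len(sum(trav0))
  cell_of_vid <- which(trav0)
  g <- igraph::make_empty_graph(n = sum(trav0), directed = TRUE)
  g <- igraph::add_edges(g, rbind(edges$from, edges$to), weight = edges$w)

  ord <- order(-facilities$capacity, facilities$facility_id)
  fac <- facilities[ord, ]
  f_idx <- xy_to_cell(merged, fac$x, fac$y)
  if (anyNA(f_idx$row)) stop("facilities outside the raster extent", call. = FALSE)
  f_cell <- cbind(f_idx$row, f_idx$col)
  if (!all(trav0[f_cell])) {
    stop("some facilities sit on barrier cells; snap them first", call. = FALSE)
  }

  nr <- nrow(merged$values)
  pop <- population$values
  pop_v <- ifelse(is.na(pop), 0, pop)
  claimed <- matrix(FALSE, nr, ncol(merged$values))
  catch <- matrix(NA_real_, nr, ncol(merged$values))

  results <- purrr::map_dfr(seq_len(nrow(fac)), function(i) {
    fv <- vid[f_cell[i, , drop = FALSE]]
    claimed_v <- claimed[cell_of_vid]
    d <- as.numeric(igraph::distances(g, v = fv, mode = "in",
                                      algorithm = "dijkstra")[1, ])
    cand <- which(is.finite(d) & d <= max_time & !claimed_v)
    cand_cells <- cell_of_vid[cand]
    o <- order(d[cand], (cand_cells - 1L) %% nr + 1L,
               (cand_cells - 1L) %/% nr + 1L)
    cand <- cand[o]
    served <- 0
    n_cl <- 0L
    stop_reason <- "max_travel_time"
    t_used <- 0
    for (v in cand) {
      p <- pop_v[cell_of_vid[v]]
      if (served + p > fac$capacity[i] + 1e-9) {
        stop_reason <- "max_capacity"
        break
      }
      served <- served + p
      n_cl <- n_cl + 1L
      t_used <- d[v]
      claimed[cell_of_vid[v]] <<- TRUE
      catch[cell_of_vid[v]] <<- i
    }
    tibble::tibble(
      facility_id = fac$facility_id[i], capacity = fac$capacity[i],
      served_population = served, n_cells = n_cl,
      stop_reason = stop_reason,
      max_time_used = if (n_cl) t_used else NA_real_
    )
  })

  served_m <- matrix(0, nr, ncol(merged$values))
  served_m[claimed] <- pop_v[claimed]
  unserved_m <- pop_v - served_m
  mk <- function(m, nodata = -9999) {
    raster_grid(m, merged$origin_x, merged$origin_y, merged$cell_size,
                crs = merged$crs, nodata = nodata)
  }
  structure(
    list(
      results = results,
      catchments = mk(catch, 255),
      served = mk(served_m),
      unserved = mk(unserved_m),
      max_time = max_time,
      scenario_name = attr(scenario, "scenario_name") %||% ""
    ),
    class = "catchment_set"
  )
}

#' @export
print.catchment_set <- function(x, ...) {
  tot <- sum(x$served$values, na.rm = TRUE) + sum(x$unserved$values, na.rm = TRUE)
  cat("<catchment_set> ", nrow(x$results), " facilities, max time ",
      x$max_time, " h\n", sep = "")
  cat(sprintf("  served %.1f of %.1f persons (%.1f%%)\n",
              sum(x$results$served_population), tot,
              100 * sum(x$results$served_population) / tot))
  invisible(x)
}

#' Summarize a coverage analysis
#'
#' Percentage of the population covered/uncovered and the share of
#' facilities stopping on each criterion (maximum travel time vs maximum
#' capacity).
#'
#' @param catchments A `catchment_set` from [delineate_catchments()].
#' @return One-row tibble: `pct_covered`, `pct_uncovered`,
#'   `pct_facilities_max_travel_time`, `pct_facilities_max_capacity`.
#' @export
coverage_summary <- function(catchments) {
  res <- catchments$results
  stopifnot(nrow(res) > 0)
  total <- sum(catchments$served$values, na.rm = TRUE) +
    sum(catchments$unserved$values, na.rm = TRUE)
  served <- sum(res$served_population)
  tibble::tibble(
    pct_covered = 100 * served / total,
    pct_uncovered = 100 * (total - served) / total,
    pct_facilities_max_travel_time =
      100 * mean(res$stop_reason == "max_travel_time"),
    pct_facilities_max_capacity =
      100 * mean(res$stop_reason == "max_capacity")
  )
}
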