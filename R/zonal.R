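#' Zonal population-coverage statistics
#'
#' Aggregates served and total population within administrative zones
#' (medical blocks). Zones are supplied as a categorical raster of zone
#' codes; cells are assigned by their centre, so every non-`NA` cell
#' belongs to exactly one zone and zone sums partition the district
#' totals exactly.
#'
#' @param served Served-population [raster_grid()] (from
#'   [delineate_catchments()]).
#' @param population Total (barrier-corrected) population [raster_grid()].
#' @param zones Categorical [raster_grid()] of zone codes.
#' @param zone_names Optional tibble `code`, `zone` mapping codes to
#'   block names.
#' @return Tibble `zone`, `population`, `served`, `pct_covered`.
#' @export
zonal_coverage <- function(served, population, zones, zone_names = NULL) {
  assert_same_frame(served, population, zones)
  z <- as.vector(zones$values)
  tot <- as.vector(population$values)
  srv <- as.vector(served$values)
  tot[is.na(tot)] <- 0
  srv[is.na(srv)] <- 0
  out <- tibble::tibble(code = z, population = tot, served = srv) |>
    dplyr::filter(!is.na(.data$code)) |>
    dplyr::group_by(.data$code) |>
    dplyr::summarise(
      population = sum(.data$population),
      served = sum(.data$served),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_covered = ifelse(.data$population > 0,
                           100 * .data$served / .data$population, NA_real_)
    )
  if (!is.null(zone_names)) {
    out <- dplyr::left_join(out, zone_names, by = "code") |>
      dplyr::relocate("zone")
  }
  out
}

#' Travel-time vs cumulative-population correlation per zone
#'
#' For each zone, the Pearson correlation between a vector of travel-time
#' thresholds and the cumulative population reachable within each
#' threshold. A low correlation flags a block whose population is not
#' spread evenly outward from its facilities — the signature of a
#' hard-to-reach block. When the cumulative vector is constant the
#' correlation is undefined and flagged (`defined = FALSE`).
#'
#' @param surface A `travel_surface`.
#' @param population Population [raster_grid()].
#' @param zones Categorical zone [raster_grid()].
#' @param thresholds Travel-time thresholds in hours (>= 3 values);
#'   default `c(1, 2, 3, 4)` mirrors the four incremental zones.
#' @param zone_names Optional tibble `code`, `zone`.
#' @return Tibble `code` (and `zone`), `r`, `defined`, plus the list
#'   column `cumulative` of per-threshold population vectors.
#' @export
time_population_correlation <- function(surface, population, zones,
                                        thresholds = c(1, 2, 3, 4),
                                        zone_names = NULL) {
  stopifnot(length(thresholds) >= 3)
  time <- surface$time
  assert_same_frame(time, population, zones)
  t_v <- as.vector(time$values)
  p_v <- as.vector(population$values)
  z_v <- as.vector(zones$values)
  p_v[is.na(p_v)] <- 0
  codes <- sort(unique(z_v[!is.na(z_v)]))
  out <- purrr::map_dfr(codes, function(cd) {
    in_zone <- !is.na(z_v) & z_v == cd
    cum <- vapply(
      thresholds,
      function(th) sum(p_v[in_zone & !is.na(t_v) & t_v <= th]),
      numeric(1)
    )
    defined <- stats::sd(cum) > 0
    tibble::tibble(
      code = cd,
      r = if (defined) stats::cor(thresholds, cum) else NA_real_,
      defined = defined,
      cumulative = list(stats::setNames(cum, paste0(thresholds, "h")))
    )
  })
  if (!is.null(zone_names)) {
    out <- dplyr::left_join(out, zone_names, by = "code") |>
      dplyr::relocate("zone")
  }
  out
}
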