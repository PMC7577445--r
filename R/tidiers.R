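#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a catchment analysis
#'
#' One row per facility: capacity, served population, number of claimed
#' cells, stopping reason and the largest travel time used.
#'
#' @param x A `catchment_set` from [delineate_catchments()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy catchment_set
#' @export
tidy.catchment_set <- function(x, ...) {
  x$results
}

#' Glance at a catchment analysis
#'
#' One-row summary: totals, coverage percentages and stop-reason shares.
#'
#' @param x A `catchment_set`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance catchment_set
#' @export
glance.catchment_set <- function(x, ...) {
  dplyr::mutate(
    coverage_summary(x),
    n_facilities = nrow(x$results),
    total_served = sum(x$results$served_population),
    max_time_h = x$max_time,
    .before = 1
  )
}

#' Tidy a travel-time surface
#'
#' @param x A `travel_surface`.
#' @param ... Passed to [as_tibble.raster_grid()].
#' @return Tibble of cells with `time_h`, plus scenario/service columns.
#' @method tidy travel_surface
#' @export
tidy.travel_surface <- function(x, ...) {
  as_tibble(x$time, ...) |>
    dplyr::rename(time_h = "value") |>
    dplyr::mutate(scenario = x$scenario_name, service = x$service)
}
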