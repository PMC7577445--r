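#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster grid
#'
#' @param object A [raster_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot raster_grid
#' @export
autoplot.raster_grid <- function(object, ...) {
  as_tibble(object, drop_na = TRUE) |>
    ggplot2::ggplot(ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
}

#' Plot a travel-time surface with its incremental zones
#'
#' @param object A `travel_surface`.
#' @param zones Plot the four incremental zones instead of continuous
#'   hours.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot travel_surface
#' @export
autoplot.travel_surface <- function(object, zones = FALSE, ...) {
  if (zones) {
    z <- classify_time_zones(object)
    labs <- time_zone_labels()
    as_tibble(z, drop_na = TRUE) |>
      dplyr::mutate(zone = factor(labs[.data$value], levels = labs)) |>
      ggplot2::ggplot(ggplot2::aes(.data$x, .data$y, fill = .data$zone)) +
      ggplot2::geom_raster() +
      ggplot2::coord_equal() +
      ggplot2::scale_fill_viridis_d(direction = -1) +
      ggplot2::labs(
        x = "easting (m)", y = "northing (m)", fill = "travel time",
        title = paste(object$scenario_name, object$service)
      )
  } else {
    autoplot(object$time) +
      ggplot2::labs(
        fill = "hours",
        title = paste(object$scenario_name, object$service)
      )
  }
}

#' Map served and unserved population of a coverage analysis
#'
#' @param catchments A `catchment_set`.
#' @return A ggplot of per-cell served fraction.
#' @export
plot_coverage <- function(catchments) {
  srv <- as_tibble(catchments$served) |>
    dplyr::rename(served = "value")
  uns <- as_tibble(catchments$unserved) |>
    dplyr::select("row", "col", unserved = "value")
  dplyr::left_join(srv, uns, by = c("row", "col")) |>
    dplyr::filter(.data$served + .data$unserved > 0) |>
    dplyr::mutate(frac = .data$served / (.data$served + .data$unserved)) |>
    ggplot2::ggplot(ggplot2::aes(.data$x, .data$y, fill = .data$frac)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "easting (m)", y = "northing (m)",
                  fill = "share of cell\npopulation served")
}
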