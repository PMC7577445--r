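#' Count facilities within a radius of each village
#'
#' Planar Euclidean ("as the crow flies") distance in the projected CRS;
#' a facility exactly on the radius is counted (closed disc).
#'
#' @param villages Tibble with `x`, `y` columns (metres).
#' @param facilities Tibble with `x`, `y` columns (metres).
#' @param radius Radius in metres.
#' @return Integer vector, one count per village.
#' @export
facilities_within <- function(villages, facilities, radius) {
  stopifnot(radius > 0)
  if (nrow(facilities) == 0) return(integer(nrow(villages)))
  vapply(seq_len(nrow(villages)), function(i) {
    d2 <- (facilities$x - villages$x[i])^2 + (facilities$y - villages$y[i])^2
    sum(d2 <= radius^2)
  }, integer(1))
}

#' Default buffer radii per service package
#'
#' Two-ring Euclidean buffers: 2 km and 5 km for ambulatory/immunization
#' care, 5 km and 10 km for delivery and inpatient care.
#'
#' @return Tibble with columns `service`, `radius_m`.
#' @export
default_buffer_specs <- function() {
  tibble::tibble(
    service = rep(c("ambulatory_immunization", "delivery", "inpatient"),
                  each = 2),
    radius_m = c(2000, 5000, 5000, 10000, 5000, 10000)
  )
}

#' Tabulate village proximity to service-providing facilities
#'
#' For each service package and buffer radius, the percentage of villages
#' with no facility, exactly one facility, and more than one facility
#' providing that service within the radius. Facilities are filtered by
#' their logical service-flag column (`ambulatory_immunization`,
#' `delivery`, `inpatient`).
#'
#' @param villages Tibble with `x`, `y`.
#' @param facilities Tibble with `x`, `y` and logical service columns.
#' @param specs Tibble `service`, `radius_m`; defaults to
#'   [default_buffer_specs()].
#' @return Tibble `service`, `radius_m`, `pct_none`, `pct_one`,
#'   `pct_more_than_one` (each row sums to 100 within rounding).
#' @export
proximity_table <- function(villages, facilities,
                            specs = default_buffer_specs()) {
  stopifnot(nrow(villages) > 0)
  purrr::pmap_dfr(specs, function(service, radius_m) {
    if (!service %in% names(facilities)) {
      stop("facilities table lacks service column '", service, "'",
           call. = FALSE)
    }
    fac <- dplyr::filter(facilities, .data[[service]])
    n <- facilities_within(villages, fac, radius_m)
    tibble::tibble(
      service = service,
      radius_m = radius_m,
      pct_none = 100 * mean(n == 0),
      pct_one = 100 * mean(n == 1),
      pct_more_than_one = 100 * mean(n > 1)
    )
  })
}
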