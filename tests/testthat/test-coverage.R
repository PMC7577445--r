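test_that("capacity formulas match direct arithmetic and scale as expected", {
  expect_equal(outpatient_capacity(3, 20, 300, 2), 9000)
  expect_equal(outpatient_capacity(0, 20, 300, 2), 0) # unstaffed
  # doubling demand halves capacity; both formulas are proportional
  expect_equal(outpatient_capacity(3, 20, 300, 4),
               outpatient_capacity(3, 20, 300, 2) / 2)
  expect_equal(inpatient_capacity(30, 0.8, 365, 0.05, 5), 35040)
  expect_equal(inpatient_capacity(30, 0.8, 365, 0.05, 2.5),
               2 * inpatient_capacity(30, 0.8, 365, 0.05, 5))
  expect_warning(out <- inpatient_capacity(30, 0, 365, 0.05, 5), "degenerate")
  expect_equal(out, 0)
  expect_error(outpatient_capacity(3, 20, 300, 0), "> 0")
  expect_error(inpatient_capacity(30, 0.8, 365, 0, 5), "> 0")
})

test_that("tier dispatch applies the right capacity formula", {
  fac <- tibble::tibble(
    tier = c("SC", "CHC"),
    workers = c(3, NA), patients_per_day = c(20, NA),
    working_days = c(300, 365), visits_per_capita = c(2, NA),
    beds = c(NA, 30), occupancy = c(NA, 0.8),
    admittances_per_capita = c(NA, 0.05), alos = c(NA, 5)
  )
  expect_equal(facility_capacities(fac)$capacity, c(9000, 35040))
})

test_that("barrier population correction conserves totals exactly", {
  merged <- raster_grid(matrix(c(1, 1, 6, 1), 2, 2), 0, 0, 10, nodata = 255)
  pop <- raster_grid(matrix(c(10, 20, 5, 0), 2, 2), 0, 0, 10)
  out <- correct_population_off_barriers(pop, merged)
  expect_equal(sum(out$values), 35)
  expect_equal(out$values[1, 2], 0) # barrier cell (row 1, col 2) emptied
  # its 5 persons moved to the unique nearest land cell
  expect_equal(out$values[1, 1], 15)
  # no barrier population: identity
  pop2 <- raster_grid(matrix(c(10, 20, 0, 0), 2, 2), 0, 0, 10)
  expect_identical(correct_population_off_barriers(pop2, merged)$values,
                   pop2$values)
})

test_that("equidistant redistribution targets break ties lexicographically", {
  merged <- raster_grid(matrix(c(1, 1, 6, 1, 1), 1, 5), 0, 0, 10, nodata = 255)
  pop <- raster_grid(matrix(c(0, 0, 7, 0, 0), 1, 5), 0, 0, 10)
  out <- correct_population_off_barriers(pop, merged)
  # cells (1,2) and (1,4) tie at 10 m; lowest column wins
  expect_equal(out$values[1, 2], 7)
  expect_equal(out$values[1, 4], 0)
})

test_that("an unconstrained facility claims everything within reach", {
  merged <- raster_grid(matrix(4, 3, 3), 0, 0, 100, nodata = 255)
  dem <- flat_grid(3, 3)
  pop <- raster_grid(matrix(10, 3, 3), 0, 0, 100)
  fac <- tibble::tibble(facility_id = "A", x = 150, y = 150, capacity = 1e6)
  cs <- delineate_catchments(fac, merged, dem, pop, scenario_table(1), 5)
  expect_equal(cs$results$stop_reason, "max_travel_time")
  expect_equal(cs$results$served_population, 90)
  expect_equal(sum(is.na(cs$catchments$values)), 0)
  expect_equal(sum(cs$unserved$values), 0)
})

test_that("capacity stops the claim in ascending travel-time order", {
  # 3x3 uniform walk grid, 10 persons/cell, centre facility with room for 50:
  # the facility cell plus the four orthogonal neighbours are claimed
  merged <- raster_grid(matrix(4, 3, 3), 0, 0, 100, nodata = 255)
  dem <- flat_grid(3, 3)
  pop <- raster_grid(matrix(10, 3, 3), 0, 0, 100)
  fac <- tibble::tibble(facility_id = "A", x = 150, y = 150, capacity = 50)
  cs <- delineate_catchments(fac, merged, dem, pop, scenario_table(1), 5)
  expect_equal(cs$results$stop_reason, "max_capacity")
  expect_equal(cs$results$served_population, 50)
  expect_equal(cs$results$n_cells, 5L)
  claimed <- !is.na(cs$catchments$values)
  expect_true(claimed[2, 2] && claimed[1, 2] && claimed[2, 1] &&
                claimed[2, 3] && claimed[3, 2])
  # zero capacity: nothing served
  fac0 <- tibble::tibble(facility_id = "A", x = 150, y = 150, capacity = 0)
  cs0 <- delineate_catchments(fac0, merged, dem, pop, scenario_table(1), 5)
  expect_equal(cs0$results$served_population, 0)
  expect_equal(cs0$results$stop_reason, "max_capacity")
})

test_that("facilities with disjoint reach are order-independent", {
  m <- matrix(4, 3, 5)
  m[, 3] <- 6 # river column splits the grid
  merged <- raster_grid(m, 0, 0, 100, nodata = 255)
  dem <- flat_grid(3, 5)
  pop <- raster_grid(matrix(10, 3, 5), 0, 0, 100)
  fac_ab <- tibble::tibble(
    facility_id = c("A", "B"), x = c(50, 450), y = 150,
    capacity = c(1000, 2000)
  )
  fac_ba <- fac_ab[2:1, ]
  fac_ba$capacity <- rev(fac_ba$capacity)  # flip processing order
  cs1 <- delineate_catchments(fac_ab, merged, dem, pop, scenario_table(1), 5)
  cs2 <- delineate_catchments(fac_ba, merged, dem, pop, scenario_table(1), 5)
  srv <- function(cs) {
    dplyr::arrange(cs$results, facility_id)$served_population
  }
  expect_equal(srv(cs1), c(60, 60))
  expect_equal(srv(cs2), c(60, 60))
})

test_that("catchments conserve population, are exclusive, and respect caps", {
  ls <- small_landscape()
  fac <- dplyr::filter(ls$facilities, ambulatory_immunization)
  cs <- delineate_catchments(fac, ls$merged, ls$dem, ls$population_corrected,
                             scenario_table(1), 1)
  total <- sum(ls$population_corrected$values)
  served <- sum(cs$served$values, na.rm = TRUE)
  unserved <- sum(cs$unserved$values, na.rm = TRUE)
  expect_lt(abs(served + unserved - total) / total, 1e-6)
  # exclusivity: claimed cell count equals the summed per-facility counts
  expect_equal(sum(!is.na(cs$catchments$values)), sum(cs$results$n_cells))
  expect_true(all(cs$results$served_population <=
                    cs$results$capacity + 1e-9))
  expect_true(all(cs$results$max_time_used <= cs$max_time + 1e-12,
                  na.rm = TRUE))
  # coverage summary is consistent
  sm <- coverage_summary(cs)
  expect_equal(sm$pct_covered + sm$pct_uncovered, 100)
  expect_equal(
    sm$pct_facilities_max_travel_time + sm$pct_facilities_max_capacity, 100
  )
  # tidy/glance accessors expose the same numbers
  expect_equal(sum(tidy(cs)$served_population), served)
  expect_equal(glance(cs)$total_served, served)
})

test_that("with infinite capacity coverage reduces to pure accessibility", {
  ls <- small_landscape()
  fac <- dplyr::filter(ls$facilities, ambulatory_immunization)
  fac$capacity <- Inf
  cs <- delineate_catchments(fac, ls$merged, ls$dem, ls$population_corrected,
                             scenario_table(1), 1)
  sf <- build_speed_surface(ls$merged, scenario_table(1))
  surf <- travel_time_toward(fac, sf$speed, sf$walking_mask, ls$dem)
  reachable <- !is.na(surf$time$values) & surf$time$values <= 1
  want <- sum(ls$population_corrected$values[reachable])
  expect_equal(sum(cs$results$served_population), want, tolerance = 1e-9)
})
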