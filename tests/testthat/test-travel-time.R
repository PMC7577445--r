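test_that("travel time matches closed forms on uniform grids", {
  # facility at the west end of a 1x3 strip, 1 km cells, 2.5 km/h
  s <- uniform_surface(1, 3, 2.5, cell_size = 1000)
  fac <- tibble::tibble(facility_id = "f", x = 500, y = 500)
  surf <- travel_time_toward(fac, s$speed, s$walking_mask, s$dem)
  expect_equal(surf$time$values[1, 1], 0)
  expect_equal(surf$time$values[1, 3], 2.0 / 2.5)
  # diagonal neighbour: sqrt(2) weighting
  s2 <- uniform_surface(2, 2, 3, cell_size = 100)
  fac2 <- tibble::tibble(facility_id = "f", x = 50, y = 150)
  surf2 <- travel_time_toward(fac2, s2$speed, s2$walking_mask, s2$dem)
  expect_equal(surf2$time$values[2, 2], 0.1 * sqrt(2) / 3)
})

test_that("on flat ground walking cells are slowed by the Tobler factor", {
  s <- uniform_surface(1, 2, 2.5, cell_size = 1000)
  s$walking_mask$values[] <- 1
  fac <- tibble::tibble(facility_id = "f", x = 500, y = 500)
  surf <- travel_time_toward(fac, s$speed, s$walking_mask, s$dem)
  expect_equal(surf$time$values[1, 2], 1 / (2.5 * exp(-0.175)))
})

test_that("anisotropy: downhill toward the facility is faster than uphill", {
  # facility at the valley end of a 1x3 slope
  s <- uniform_surface(1, 3, 5, cell_size = 100)
  s$walking_mask$values[] <- 1
  s$dem$values[] <- c(0, 20, 40) # rises eastward
  fac_w <- tibble::tibble(facility_id = "f", x = 50, y = 50)
  fac_e <- tibble::tibble(facility_id = "f", x = 250, y = 50)
  t_down <- travel_time_toward(fac_w, s$speed, s$walking_mask, s$dem)
  t_up <- travel_time_toward(fac_e, s$speed, s$walking_mask, s$dem)
  # walking toward the west facility descends (S = -0.2 per edge);
  # walking toward the east facility climbs (S = +0.2)
  v_down <- 5 * exp(-3.5 * abs(-0.2 + 0.05))
  v_up <- 5 * exp(-3.5 * abs(0.2 + 0.05))
  expect_equal(t_down$time$values[1, 3], 0.1 / v_down + 0.1 / v_down)
  expect_equal(t_up$time$values[1, 1], 0.2 / v_up)
  expect_lt(t_down$time$values[1, 3], t_up$time$values[1, 1])
})

test_that("a river column disconnects the far side", {
  sp <- matrix(5, 4, 5)
  sp[, 3] <- NA
  s <- list(
    speed = raster_grid(sp, 0, 0, 100),
    walking_mask = raster_grid(matrix(0, 4, 5), 0, 0, 100, nodata = 255),
    dem = flat_grid(4, 5)
  )
  fac <- tibble::tibble(facility_id = "f", x = 50, y = 50)
  surf <- travel_time_toward(fac, s$speed, s$walking_mask, s$dem)
  expect_true(all(is.na(surf$time$values[, 3:5])))
  expect_true(all(is.finite(surf$time$values[, 1:2])))
})

test_that("small random instances match the Bellman-Ford oracle", {
  n_checked <- 0
  for (seed in 1:40) {
    inst <- random_tt_instance(seed)
    if (is.null(inst)) next
    surf <- travel_time_toward(inst$facilities, inst$speed, inst$walk,
                               inst$dem)
    want <- bf_travel_time(inst$speed_m, inst$walk_m, inst$dem_m,
                           inst$facility_cells, inst$cell_size)
    got <- surf$time$values
    got[is.na(got) & !is.na(inst$speed_m)] <- Inf
    comparable <- !is.na(inst$speed_m)
    expect_equal(got[comparable], want[comparable], tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 30)
})

test_that("time zones use closed upper bounds and propagate nodata", {
  t <- raster_grid(matrix(c(0.5, 1.0, 1.5, 2.0, 3.01, NA), 2, 3), 0, 0, 30)
  z <- classify_time_zones(t)
  expect_equal(z$values[1, 1], 1) # 0.5 h
  expect_equal(z$values[2, 1], 1) # exactly 1 h stays in the first zone
  expect_equal(z$values[1, 2], 2)
  expect_equal(z$values[2, 2], 2) # exactly 2 h
  expect_equal(z$values[1, 3], 4) # 3.01 h
  expect_true(is.na(z$values[2, 3]))
  expect_equal(attr(z, "zone_labels"), time_zone_labels())
})

test_that("village summaries tabulate zones and medians", {
  # 1x5 strip: facility at the west end, village times 0.5..3.5 h by speed
  sp <- matrix(2.5, 1, 9)
  sp[1, 5] <- NA
  s <- list(
    speed = raster_grid(sp, 0, 0, 1000),
    walking_mask = raster_grid(matrix(0, 1, 9), 0, 0, 1000, nodata = 255),
    dem = flat_grid(1, 9, cell_size = 1000)
  )
  fac <- tibble::tibble(facility_id = "f", x = 500, y = 500)
  surf <- travel_time_toward(fac, s$speed, s$walking_mask, s$dem)
  # villages at cells 2..5: times 0.4, 0.8, 1.2 h and one on the barrier
  vil <- tibble::tibble(
    village_id = paste0("V", 1:4),
    x = c(1500, 2500, 3500, 4500), y = 500
  )
  vs <- village_travel_summary(vil, surf)
  expect_equal(vs$n_unreachable, 1)
  expect_true(vs$villages$unreachable[4])
  expect_equal(vs$median_time_h, 0.8)
  expect_equal(vs$zone_shares$pct_villages, c(200 / 3, 100 / 3, 0, 0))

  # co-located villages: all in the first zone with median 0
  vs0 <- village_travel_summary(
    tibble::tibble(village_id = "V1", x = 500, y = 500), surf
  )
  expect_equal(vs0$median_time_h, 0)
  expect_equal(vs0$zone_shares$pct_villages[1], 100)
})

test_that("four villages spread across the zones give 25% each and median 2", {
  t <- raster_grid(matrix(c(0.5, 1.5, 2.5, 3.5), 1, 4), 0, 0, 100)
  surf <- structure(
    list(time = t, scenario_name = "s", service = "svc"),
    class = "travel_surface"
  )
  vil <- tibble::tibble(village_id = paste0("V", 1:4),
                        x = c(50, 150, 250, 350), y = 50)
  vs <- village_travel_summary(vil, surf)
  expect_equal(vs$zone_shares$pct_villages, rep(25, 4))
  expect_equal(vs$median_time_h, 2.0)
})

test_that("errors: no traversable facility, non-positive speeds", {
  s <- uniform_surface(2, 2, 5)
  bad_fac <- tibble::tibble(facility_id = "f", x = 1e9, y = 1e9)
  expect_error(travel_time_toward(bad_fac, s$speed, s$walking_mask, s$dem),
               "extent")
  s$speed$values[1, 1] <- NA
  on_barrier <- tibble::tibble(facility_id = "f", x = 50, y = 150)
  expect_error(
    travel_time_toward(on_barrier, s$speed, s$walking_mask, s$dem),
    "traversable"
  )
  s2 <- uniform_surface(2, 2, 5)
  s2$speed$values[2, 1] <- -1
  fac <- tibble::tibble(facility_id = "f", x = 50, y = 150)
  expect_error(travel_time_toward(fac, s2$speed, s2$walking_mask, s2$dem),
               "positive")
})
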