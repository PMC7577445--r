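test_that("generation is bit-identical under a fixed seed", {
  cfg <- landscape_config(seed = 7, n_rows = 40, n_cols = 40,
                          n_villages = 15,
                          n_facilities_by_tier = c(SC = 5, PHC = 2,
                                                   CHC = 1, DH = 1),
                          total_population = 3000)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a$dem$values, b$dem$values)
  expect_identical(a$landcover$values, b$landcover$values)
  expect_identical(a$population$values, b$population$values)
  expect_identical(a$facilities, b$facilities)
  expect_identical(a$villages, b$villages)
  expect_identical(a$roads$geometry, b$roads$geometry)
})

test_that("population is non-negative, conserved, and valley-concentrated", {
  ls <- small_landscape()
  pop <- ls$population$values
  expect_true(all(pop >= 0))
  total <- ls$config$total_population
  expect_lt(abs(sum(pop) - total) / total, 1e-6)
  # population-weighted elevation sits well below the mean elevation
  mean_elev <- mean(ls$dem$values)
  pw_elev <- sum(pop * ls$dem$values) / sum(pop)
  expect_lt(pw_elev, mean_elev)
  # a small share sits on river barriers to exercise the correction
  on_barrier <- ls$merged$values %in% barrier_codes()
  barrier_share <- sum(pop[on_barrier]) / total
  expect_gt(barrier_share, 0.005)
  expect_lt(barrier_share, 0.03)
})

test_that("facility service mix matches the configured fractions", {
  ls <- small_landscape()
  fac <- ls$facilities
  n <- nrow(fac)
  expect_true(all(fac$ambulatory_immunization))
  expect_equal(sum(fac$delivery), round(ls$config$delivery_fraction * n))
  expect_equal(sum(fac$inpatient), round(ls$config$inpatient_fraction * n))
  # delivery/inpatient concentrate in the higher tiers
  expect_true(all(fac$delivery[fac$tier %in% c("DH", "CHC")]))
  expect_true(all(fac$capacity > 0))
  # the default configuration mirrors the published service-availability
  # proportions (34 delivery and 28 inpatient of 185 facilities)
  dflt <- landscape_config()
  expect_equal(dflt$delivery_fraction, 34 / 185)
  expect_equal(dflt$inpatient_fraction, 28 / 185)
})

test_that("facilities and villages avoid barriers; roads never touch water", {
  ls <- small_landscape()
  idx <- accesscape:::xy_to_cell(ls$merged, ls$facilities$x, ls$facilities$y)
  codes <- ls$merged$values[cbind(idx$row, idx$col)]
  expect_false(any(codes %in% barrier_codes()))
  vidx <- accesscape:::xy_to_cell(ls$merged, ls$villages$x, ls$villages$y)
  vcodes <- ls$merged$values[cbind(vidx$row, vidx$col)]
  expect_false(any(vcodes %in% barrier_codes()))
  expect_equal(
    sum(!is.na(ls$roads_raster$values) & !is.na(ls$rivers_raster$values)), 0
  )
})

test_that("the road network rasterizes to one connected component", {
  ls <- small_landscape()
  r <- ls$roads_raster$values
  cells <- which(!is.na(r), arr.ind = TRUE)
  id <- seq_len(nrow(cells))
  key <- paste(cells[, 1], cells[, 2])
  lookup <- stats::setNames(id, key)
  edges <- NULL
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- paste(cells[, 1] + dr, cells[, 2] + dc)
    hit <- !is.na(lookup[nb])
    edges <- rbind(edges, cbind(id[hit], lookup[nb[hit]]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
  # all three tiers are present, tertiary split by passability
  expect_setequal(unique(r[!is.na(r)]), 8:12)
})

test_that("villages partition into three blocks with a border strip", {
  ls <- small_landscape()
  vil <- ls$villages
  expect_setequal(unique(vil$zone), c("Mandi", "Surankote", "Mendhar"))
  expect_equal(sum(table(vil$zone)), nrow(vil))
  n_border <- floor(ls$config$border_fraction * nrow(vil))
  expect_equal(sum(vil$border), n_border)
  # border villages are the westernmost ones
  expect_lte(max(vil$x[vil$border]), min(vil$x[!vil$border]))
  # zone raster covers the grid and partitions cells
  expect_false(anyNA(ls$zones$values))
  expect_setequal(unique(as.vector(ls$zones$values)), 1:3)
})

test_that("landscapes serialize to plain formats and read back", {
  cfg <- landscape_config(seed = 3, n_rows = 30, n_cols = 30,
                          n_villages = 8,
                          n_facilities_by_tier = c(SC = 3, PHC = 1,
                                                   CHC = 1, DH = 1),
                          total_population = 1000)
  ls <- generate_landscape(cfg)
  dir <- withr::local_tempdir()
  write_landscape(ls, dir)
  dem <- read_raster(file.path(dir, "dem.asc"))
  expect_equal(dem$values, ls$dem$values)
  fac <- readr::read_csv(file.path(dir, "facilities.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(fac), 6)
  roads <- read_lines_geojson(file.path(dir, "roads.geojson"))
  expect_equal(nrow(roads), nrow(ls$roads))
  expect_true(file.exists(file.path(dir, "scenarios", "scenario1.csv")))
})

test_that("infeasible configurations are rejected", {
  expect_error(
    landscape_config(n_rows = 10, n_cols = 10,
                     n_facilities_by_tier = c(SC = 90, PHC = 10,
                                              CHC = 5, DH = 1),
                     n_villages = 50),
    "more facilities"
  )
  expect_error(landscape_config(delivery_fraction = 1.2))
  expect_error(landscape_config(n_facilities_by_tier = c(SC = 1)), "tier")
})
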