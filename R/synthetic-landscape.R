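#' Configuration for the synthetic district generator
#'
#' Defines a self-contained mountainous district emulating the structure
#' the accessibility analysis assumes: strong relief with a low valley, a
#' braided river barrier, a sparse three-tier road tree east of the
#' river (the western border strip is road-free), population clustered
#' in low-elevation settlement cells, and a facility network in which
#' every facility offers ambulatory/immunization care but only small
#' fractions offer delivery (34/185) and inpatient (28/185) care —
#' matching the service-availability proportions of the district that
#' motivated the design. The default 9 km x 9 km extent is a scaled-down
#' district that preserves the real system's per-facility area (roughly
#' one facility per 6-9 square km), population density (about 285
#' persons per square km) and tier mix, so travel-time and coverage
#' distributions have realistic magnitudes.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_rows,n_cols Grid dimensions.
#' @param cell_size Cell size in metres (30 m, the analysis resolution).
#' @param relief_amplitude Elevation range above the valley floor, metres.
#' @param base_elevation Valley-floor elevation, metres.
#' @param n_facilities_by_tier Named counts for tiers `SC`, `PHC`, `CHC`,
#'   `DH`.
#' @param delivery_fraction,inpatient_fraction Fractions of facilities
#'   equipped for delivery / inpatient care.
#' @param n_villages Number of village centroids.
#' @param border_fraction Fraction of villages flagged as conflict-prone
#'   border villages (the westernmost ones).
#' @param total_population Total district population (persons).
#' @param river_population_fraction Share of population deliberately
#'   placed on river (barrier) cells, emulating the barrier-misplacement
#'   of gridded population products (about 1.2% in practice).
#' @param origin_x,origin_y Lower-left corner (metres, projected CRS).
#' @param crs CRS identifier.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(seed = 1L,
                             n_rows = 300L, n_cols = 300L,
                             cell_size = 30,
                             relief_amplitude = 1500,
                             base_elevation = 1000,
                             n_facilities_by_tier =
                               c(SC = 9L, PHC = 3L, CHC = 1L, DH = 1L),
                             delivery_fraction = 34 / 185,
                             inpatient_fraction = 28 / 185,
                             n_villages = 60L,
                             border_fraction = 0.6,
                             total_population = 23000,
                             river_population_fraction = 0.012,
                             origin_x = 400000, origin_y = 3720000,
                             crs = "EPSG:32644") {
  cfg <- list(
    seed = as.integer(seed), n_rows = as.integer(n_rows),
    n_cols = as.integer(n_cols), cell_size = cell_size,
    relief_amplitude = relief_amplitude, base_elevation = base_elevation,
    n_facilities_by_tier = n_facilities_by_tier,
    delivery_fraction = delivery_fraction,
    inpatient_fraction = inpatient_fraction,
    n_villages = as.integer(n_villages),
    border_fraction = border_fraction,
    total_population = total_population,
    river_population_fraction = river_population_fraction,
    origin_x = origin_x, origin_y = origin_y, crs = crs
  )
  fr <- c(cfg$delivery_fraction, cfg$inpatient_fraction,
          cfg$border_fraction, cfg$river_population_fraction)
  stopifnot(all(fr >= 0 & fr <= 1), cfg$n_rows >= 10, cfg$n_cols >= 10,
            cfg$cell_size > 0, cfg$relief_amplitude > 0,
            all(cfg$n_facilities_by_tier >= 0),
            sum(cfg$n_facilities_by_tier) >= 1,
            cfg$n_villages >= 1, cfg$total_population > 0)
  if (!all(c("SC", "PHC", "CHC", "DH") %in% names(cfg$n_facilities_by_tier))) {
    stop("n_facilities_by_tier must name SC, PHC, CHC and DH", call. = FALSE)
  }
  if (sum(cfg$n_facilities_by_tier) + cfg$n_villages > cfg$n_rows * cfg$n_cols) {
    stop("more facilities/villages than grid cells", call. = FALSE)
  }
  structure(cfg, class = "landscape_config")
}

# sum of random Gaussian bumps, rescaled to [0, 1]
smooth_field <- function(u, v, n_bumps = 6, len = 0.18) {
  f <- matrix(0, nrow(u), ncol(u))
  for (k in seq_len(n_bumps)) {
    cu <- stats::runif(1); cv <- stats::runif(1)
    s <- len * stats::runif(1, 0.6, 1.4)
    a <- stats::runif(1, 0.3, 1)
    f <- f + a * exp(-((u - cu)^2 + (v - cv)^2) / (2 * s^2))
  }
  rng <- range(f)
  if (diff(rng) == 0) return(f * 0)
  (f - rng[1]) / diff(rng)
}

# river channel position (as a fraction of width) at relative northing v
river_path <- function(v, phase) {
  0.33 + 0.06 * sin(2 * pi * 1.3 * v + phase)
}

#' Generate a synthetic district landscape
#'
#' Produces every input layer the pipeline needs, deterministically under
#' the configuration seed. See [landscape_config()] for what the
#' landscape emulates.
#'
#' @param config A [landscape_config()].
#' @return A list with elements `dem`, `landcover` (7 generic classes),
#'   `roads` and `rivers` (line tibbles with `geometry` list-columns),
#'   `population`, `facilities` (tibble with service flags, capacity
#'   inputs and derived `capacity`), `villages` (tibble with `zone` and
#'   `border` flags), `zones` (zone-code [raster_grid()]), `zone_names`,
#'   and the echoed `config`.
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  nr <- config$n_rows; nc <- config$n_cols; cs <- config$cell_size
  width <- nc * cs; height <- nr * cs
  xmin <- config$origin_x; ymin <- config$origin_y
  ymax <- ymin + height
  mk <- function(m, nodata = -9999) {
    raster_grid(m, xmin, ymin, cs, crs = config$crs, nodata = nodata)
  }
  u <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  v <- matrix(rep((seq_len(nr) - 0.5) / nr, times = nc), nr, nc)

  # --- elevation: ridges + northward trend, valley carved along the river
  phase <- stats::runif(1, 0, 2 * pi)
  ridges <- smooth_field(u, v, n_bumps = 7, len = 0.22)
  valley <- exp(-(u - river_path(v, phase))^2 / (2 * 0.09^2))
  field <- 0.85 * ridges + 0.45 * (1 - v) - 0.9 * valley
  field <- (field - min(field)) / diff(range(field))
  dem <- mk(config$base_elevation + config$relief_amplitude * field)
  rel <- field

  # --- rivers: main channel plus a braid rejoining mid-reach
  vv <- seq(0, 1, by = 0.01)
  xy_river <- function(frac_x, frac_v) {
    cbind(xmin + frac_x * width, ymax - frac_v * height)
  }
  main <- xy_river(river_path(vv, phase), vv)
  bv <- seq(0.4, 0.6, by = 0.01)
  braid <- xy_river(
    river_path(bv, phase) + 0.04 * sin(pi * (bv - 0.4) / 0.2), bv
  )
  rivers <- tibble::tibble(
    feature_id = 1:2, part = 1L,
    name = c("main_channel", "braid"),
    code = barrier_codes()[1],
    geometry = list(main, braid)
  )
  river_r <- rasterize_lines(rivers, dem)
  on_river <- !is.na(river_r$values)

  # --- generic land cover (7 classes); forest-dominant like a Himalayan
  #     district, snow on the highest ground, crops/settlement in the valley
  lc <- matrix(1, nr, nc)                                   # Forestland
  g_grass <- smooth_field(u, v, 5, 0.15)
  g_waste <- smooth_field(u, v, 5, 0.12)
  g_crop <- smooth_field(u, v, 5, 0.2)
  g_settle <- smooth_field(u, v, 6, 0.1)
  lc[g_grass > stats::quantile(g_grass, 0.8)] <- 2          # Grassland
  lc[g_waste > stats::quantile(g_waste, 0.9)] <- 5          # Wasteland
  near_valley <- abs(u - river_path(v, phase)) < 0.13
  crop <- rel < 0.35 & near_valley & g_crop > stats::quantile(g_crop, 0.3)
  lc[crop] <- 3                                             # Cropland
  settle_score <- exp(-4 * rel) * exp(-abs(u - river_path(v, phase)) / 0.1) *
    (0.4 + g_settle)
  lc[settle_score >= stats::quantile(settle_score, 0.94)] <- 4  # Settlement
  pond_ctr <- which(rel < 0.25 & !on_river & u > 0.6, arr.ind = TRUE)
  if (nrow(pond_ctr)) {
    pc <- pond_ctr[sample.int(nrow(pond_ctr), 1), ]
    pd <- sqrt((row(lc) - pc[1])^2 + (col(lc) - pc[2])^2)
    lc[pd <= 2.2] <- 6                                      # a small lake
  }
  lc[rel > 0.82] <- 7                                       # Snowcapped
  landcover <- mk(lc, nodata = 255)
  is_water <- on_river | lc == 6

  # --- roads: connected 3-tier tree, entirely east of the river
  trunk_v <- seq(0, 1, by = 0.02)
  trunk_x <- river_path(trunk_v, phase) + 0.10
  trunk <- xy_river(trunk_x, trunk_v)
  v_major <- 0.88
  major_start <- xy_river(river_path(v_major, phase) + 0.10, v_major)
  major <- rbind(major_start, xy_river(0.995, v_major))
  branch_from <- function(frac_v, dx, dv, n_seg = 2) {
    p0 <- xy_river(river_path(frac_v, phase) + 0.10, frac_v)
    p2 <- p0 + c(dx * width, -dv * height)
    p2[1] <- min(max(p2[1], xmin + cs), xmin + width - cs)
    p2[2] <- min(max(p2[2], ymin + cs), ymax - cs)
    if (n_seg == 1) return(rbind(p0, p2))
    mid <- (p0 + p2) / 2 + c(stats::runif(1, -0.02, 0.02) * width,
                             stats::runif(1, -0.02, 0.02) * height)
    rbind(p0, mid, p2)
  }
  sec2 <- branch_from(0.30, 0.35, 0.12)
  terts <- list(
    branch_from(0.15, 0.18, -0.05), branch_from(0.50, 0.25, 0.06),
    branch_from(0.70, 0.15, -0.08), branch_from(0.95, 0.20, 0.02),
    rbind(sec2[3, ], sec2[3, ] + c(0.10 * width, -0.08 * height)),
    rbind(major[2, ], major[2, ] + c(-0.05 * width, -0.10 * height))
  )
  road_geoms <- c(list(major, trunk, sec2), terts)
  road_codes <- c(8, 9, 9, 10, 10, 11, 11, 12, 12)
  road_tiers <- merged_classes()$label[road_codes]
  roads <- tibble::tibble(
    feature_id = seq_along(road_geoms), part = 1L,
    tier = road_tiers, code = road_codes,
    geometry = road_geoms
  )

  # --- population: low-elevation / settlement-weighted, a small share on
  #     the river to exercise barrier correction
  w <- exp(-3 * rel)
  w[lc == 4] <- w[lc == 4] * 8
  w[lc == 3] <- w[lc == 3] * 3
  w[lc == 7] <- w[lc == 7] * 0.02
  w[is_water] <- 0
  land_share <- 1 - config$river_population_fraction
  pop <- w / sum(w) * config$total_population * land_share
  riv_cells <- which(on_river)
  if (length(riv_cells) && config$river_population_fraction > 0) {
    nb_w <- vapply(riv_cells, function(cl) {
      r0 <- (cl - 1L) %% nr + 1L; c0 <- (cl - 1L) %/% nr + 1L
      rs <- max(1, r0 - 1):min(nr, r0 + 1)
      cc <- max(1, c0 - 1):min(nc, c0 + 1)
      sum(w[rs, cc])
    }, numeric(1))
    top <- riv_cells[order(-nb_w)[seq_len(min(8L, length(riv_cells)))]]
    pop[top] <- pop[top] +
      config$total_population * config$river_population_fraction / length(top)
  }
  pop <- pop * config$total_population / sum(pop)
  population <- mk(pop)

  # --- facilities: population-seeking placement, tiered
  placeable <- which(!is_water)
  n_fac <- sum(config$n_facilities_by_tier)
  if (n_fac > length(placeable)) {
    stop("more facilities than non-barrier cells", call. = FALSE)
  }
  pop_order <- placeable[order(-pop[placeable])]
  taken <- integer(0)
  pick_spread <- function(n, min_sep_cells) {
    out <- integer(0)
    for (cl in pop_order) {
      if (length(out) == n) break
      r0 <- (cl - 1L) %% nr + 1L; c0 <- (cl - 1L) %/% nr + 1L
      all_cells <- c(taken, out)
      if (length(all_cells)) {
        rr <- (all_cells - 1L) %% nr + 1L; cc <- (all_cells - 1L) %/% nr + 1L
        if (min(sqrt((rr - r0)^2 + (cc - c0)^2)) < min_sep_cells) next
      }
      out <- c(out, cl)
    }
    if (length(out) < n) { # separation infeasible: top up densest-first
      extra <- setdiff(pop_order, c(taken, out))
      out <- c(out, extra[seq_len(n - length(out))])
    }
    out
  }
  dh_cells <- pick_spread(config$n_facilities_by_tier[["DH"]], 0)
  taken <- c(taken, dh_cells)
  chc_cells <- pick_spread(config$n_facilities_by_tier[["CHC"]], 25)
  taken <- c(taken, chc_cells)
  phc_cells <- pick_spread(config$n_facilities_by_tier[["PHC"]], 15)
  taken <- c(taken, phc_cells)
  sc_pool <- setdiff(placeable, taken)
  sc_n <- config$n_facilities_by_tier[["SC"]]
  sc_cells <- sample(sc_pool, sc_n, prob = sqrt(pop[sc_pool]) + 1e-9)
  cells <- c(dh_cells, chc_cells, phc_cells, sc_cells)
  tiers <- rep(c("DH", "CHC", "PHC", "SC"),
               times = c(length(dh_cells), length(chc_cells),
                         length(phc_cells), length(sc_cells)))
  rowi <- (cells - 1L) %% nr + 1L
  coli <- (cells - 1L) %/% nr + 1L
  ctr <- cell_centre_xy(dem, rowi, coli)
  fac <- tibble::tibble(
    facility_id = sprintf("F%03d", seq_along(cells)),
    tier = tiers, x = ctr$x, y = ctr$y,
    workers = NA_real_, patients_per_day = NA_real_,
    working_days = NA_real_, visits_per_capita = NA_real_,
    beds = NA_real_, occupancy = NA_real_,
    admittances_per_capita = NA_real_, alos = NA_real_
  )
  sc <- fac$tier == "SC"; phc <- fac$tier == "PHC"
  chc <- fac$tier == "CHC"; dh <- fac$tier == "DH"
  fac$workers[sc] <- sample(1:2, sum(sc), replace = TRUE)
  fac$patients_per_day[sc] <- sample(6:10, sum(sc), replace = TRUE)
  fac$working_days[sc] <- 200
  fac$visits_per_capita[sc] <- 2.5
  fac$workers[phc] <- sample(2:4, sum(phc), replace = TRUE)
  fac$patients_per_day[phc] <- sample(10:15, sum(phc), replace = TRUE)
  fac$working_days[phc] <- 250
  fac$visits_per_capita[phc] <- 2.5
  fac$beds[chc] <- sample(8:12, sum(chc), replace = TRUE)
  fac$occupancy[chc] <- 0.6
  fac$working_days[chc] <- 365
  fac$admittances_per_capita[chc] <- 0.05
  fac$alos[chc] <- 6
  fac$beds[dh] <- 40
  fac$occupancy[dh] <- 0.75
  fac$working_days[dh] <- 365
  fac$admittances_per_capita[dh] <- 0.05
  fac$alos[dh] <- 6
  fac <- facility_capacities(fac)

  n_del <- round(config$delivery_fraction * n_fac)
  n_inp <- round(config$inpatient_fraction * n_fac)
  pref <- order(match(fac$tier, c("DH", "CHC", "PHC", "SC")), -fac$capacity)
  fac$ambulatory <- TRUE
  fac$immunization <- TRUE
  fac$ambulatory_immunization <- TRUE
  fac$delivery <- seq_len(n_fac) %in% pref[seq_len(n_del)]
  fac$inpatient <- seq_len(n_fac) %in% pref[seq_len(n_inp)]

  # --- villages: population-weighted settlements in 3 blocks, the
  #     westernmost flagged as conflict-prone border villages
  vil_pool <- setdiff(which(!is_water & pop > 0), cells)
  vil_cells <- sample(vil_pool, config$n_villages, prob = pop[vil_pool])
  vr <- (vil_cells - 1L) %% nr + 1L
  vc <- (vil_cells - 1L) %/% nr + 1L
  vctr <- cell_centre_xy(dem, vr, vc)
  zone_code_of_col <- pmin(3L, 1L + (3L * (vc - 1L)) %/% nc)
  zone_names <- tibble::tibble(
    code = 1:3, zone = c("Mandi", "Surankote", "Mendhar")
  )
  villages <- tibble::tibble(
    village_id = sprintf("V%03d", seq_along(vil_cells)),
    x = vctr$x, y = vctr$y,
    zone = zone_names$zone[zone_code_of_col]
  )
  n_border <- floor(config$border_fraction * config$n_villages)
  border_rank <- order(villages$x, villages$village_id)
  villages$border <- seq_len(config$n_villages) %in%
    border_rank[seq_len(n_border)]

  zones <- mk(matrix(pmin(3L, 1L + (3L * (col(lc) - 1L)) %/% nc), nr, nc),
              nodata = 255)

  list(
    config = config,
    dem = dem, landcover = landcover,
    roads = roads, rivers = rivers,
    population = population,
    facilities = fac, villages = villages,
    zones = zones, zone_names = zone_names
  )
}

#' Write a generated landscape to a directory
#'
#' Serializes every layer in standard plain formats: `.asc` rasters,
#' GeoJSON line layers and CSV tables.
#'
#' @param landscape Result of [generate_landscape()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_raster(landscape$dem, file.path(dir, "dem.asc"))
  write_raster(landscape$landcover, file.path(dir, "landcover.asc"))
  write_raster(landscape$population, file.path(dir, "population.asc"))
  write_raster(landscape$zones, file.path(dir, "zones.asc"))
  write_lines_geojson(landscape$roads, file.path(dir, "roads.geojson"))
  write_lines_geojson(landscape$rivers, file.path(dir, "rivers.geojson"))
  readr::write_csv(landscape$facilities, file.path(dir, "facilities.csv"))
  readr::write_csv(landscape$villages, file.path(dir, "villages.csv"))
  readr::write_csv(landscape$zone_names, file.path(dir, "zone_names.csv"))
  make_fixture_scenarios(file.path(dir, "scenarios"))
  invisible(dir)
}
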