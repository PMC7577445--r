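# shared fixtures and the independent shortest-path oracle

# uniform raster on a simple frame
flat_grid <- function(nr, nc, value = 0, cell_size = 100, nodata = -9999) {
  raster_grid(matrix(value, nr, nc), 0, 0, cell_size,
              crs = "EPSG:32644", nodata = nodata)
}

# uniform speed surface with no slope correction (walking mask off)
uniform_surface <- function(nr, nc, speed, cell_size = 100) {
  list(
    speed = flat_grid(nr, nc, speed, cell_size),
    walking_mask = flat_grid(nr, nc, 0, cell_size, nodata = 255),
    dem = flat_grid(nr, nc, 0, cell_size)
  )
}

# one small generated landscape, reused across tests (built once per run)
small_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- landscape_config(
        seed = 42, n_rows = 60, n_cols = 60, n_villages = 30,
        n_facilities_by_tier = c(SC = 8, PHC = 3, CHC = 1, DH = 1),
        total_population = 5000
      )
      ls <- generate_landscape(cfg)
      roads_r <- rasterize_lines(ls$roads, ls$dem)
      rivers_r <- rasterize_lines(ls$rivers, ls$dem)
      ls$merged <- merge_layers(ls$landcover, roads_r, rivers_r)
      ls$roads_raster <- roads_r
      ls$rivers_raster <- rivers_r
      ls$facilities <- snap_points_off_barriers(ls$facilities, ls$merged)
      ls$population_corrected <-
        correct_population_off_barriers(ls$population, ls$merged)
      cache <<- ls
    }
    cache
  }
})

# Independent travel-time oracle: Bellman-Ford relaxation over explicit
# neighbour enumeration, with its own cost arithmetic. dist[a] is the cost
# of the cheapest directed path a -> ... -> facility; speeds on walking
# cells are slope-corrected in the direction of motion.
bf_travel_time <- function(speed_m, walk_m, dem_m, facility_cells, cell_size) {
  nr <- nrow(speed_m); nc <- ncol(speed_m)
  n <- nr * nc
  dist <- rep(Inf, n)
  dist[facility_cells] <- 0
  for (iter in seq_len(n + 1L)) {
    changed <- FALSE
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (is.na(speed_m[r, cc])) next
      a <- (cc - 1L) * nr + r
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(speed_m[r2, c2])) next
        b <- (c2 - 1L) * nr + r2
        d_m <- cell_size * sqrt(dr^2 + dc^2)
        s <- (dem_m[r2, c2] - dem_m[r, cc]) / d_m
        va <- speed_m[r, cc]
        if (walk_m[r, cc] == 1) va <- va * exp(-3.5 * abs(s + 0.05))
        vb <- speed_m[r2, c2]
        if (walk_m[r2, c2] == 1) vb <- vb * exp(-3.5 * abs(s + 0.05))
        w <- (d_m / 1000) / 2 / va + (d_m / 1000) / 2 / vb
        if (w + dist[b] < dist[a] - 1e-15) {
          dist[a] <- w + dist[b]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  matrix(dist, nr, nc)
}

# a random small travel-time instance (grids up to 6x6)
random_tt_instance <- function(seed) {
  set.seed(seed)
  nr <- sample(2:6, 1); nc <- sample(2:6, 1)
  speed <- matrix(stats::runif(nr * nc, 0.5, 50), nr, nc)
  speed[stats::runif(nr * nc) < 0.2] <- NA
  walk <- matrix(stats::rbinom(nr * nc, 1, 0.5), nr, nc)
  walk[is.na(speed)] <- NA
  dem <- matrix(stats::runif(nr * nc, 0, 400), nr, nc)
  trav <- which(!is.na(speed))
  if (!length(trav)) return(NULL)
  fac <- sample(trav, min(length(trav), sample(1:3, 1)))
  cs <- 100
  g <- function(m, nodata = -9999) raster_grid(m, 0, 0, cs, nodata = nodata)
  fr <- (fac - 1L) %% nr + 1L
  fc <- (fac - 1L) %/% nr + 1L
  list(
    speed = g(speed), walk = g(walk, 255), dem = g(dem),
    facilities = tibble::tibble(facility_id = as.character(fac),
                                x = (fc - 0.5) * cs,
                                y = (nr - fr + 0.5) * cs),
    facility_cells = fac, cell_size = cs,
    speed_m = speed, walk_m = walk, dem_m = dem
  )
}
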