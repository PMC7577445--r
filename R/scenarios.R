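#' Tobler's hiking function
#'
#' Slope-corrected walking speed `V = VF * exp(-3.5 * |S + 0.05|)`, where
#' `VF` is the flat-terrain walking speed and `S` is the dimensionless
#' slope gradient (rise over run, signed in the direction of movement).
#' Walking is fastest on a gentle 5% downhill (`S = -0.05`), where the
#' correction factor is 1; it decays exponentially on either side.
#'
#' @param v_flat Flat-terrain speed in km/h (> 0). Vectorised.
#' @param slope Dimensionless gradient dh/dx in the direction of motion.
#'   Vectorised.
#' @return Corrected speed in km/h (always > 0).
#' @examples
#' tobler_speed(5, -0.05) # 5: the optimum
#' tobler_speed(5, 0)     # 5 * exp(-0.175)
#' @export
tobler_speed <- function(v_flat, slope) {
  stopifnot(all(v_flat > 0, na.rm = TRUE))
  v_flat * exp(-3.5 * abs(slope + 0.05))
}

# Flat walking speeds by land-cover class shared by all scenarios (km/h)
.walk_speeds <- c(
  Forestland = 1.67, `Grassland/Plantation` = 1.67, Cropland = 1.67,
  Settlement = 2.5, `Wasteland/Fallow/Other` = 2.5, Waterbodies = NA,
  Snowcapped = 1.25, MajorRoad = 2.5, SecondaryRoad = 2.5,
  TertiaryAllVehicle = 2.5, TertiaryTwoWheeler = 2.5, TertiaryWalkOnly = 2.5
)

#' Built-in travel scenario tables
#'
#' Four multimodal travel scenarios over the 12 merged land-cover classes:
#' walking only (1), walking + motorcycle (2), walking + public transport
#' (3) and walking + private vehicle (4). Water is impassable under every
#' scenario. The tables ship exactly as printed in the source speed table,
#' including its scenario-3 anomaly, where major roads carry a public
#' transport speed of 1.25 km/h — slower than walking and almost
#' certainly a typographical slip. `scenario_table(3, corrected = TRUE)`
#' returns a variant with major roads at 40 km/h (the major-road speed of
#' the other motorized scenarios) for users who prefer the plausible
#' reading.
#'
#' @param scenario Integer 1-4.
#' @param corrected Use the corrected scenario-3 major-road speed
#'   (ignored for other scenarios).
#' @return A tibble with columns `class_code`, `class_label`, `mode`
#'   (`walking`, `motorcycle`, `public_transport`, `private_vehicle`) and
#'   `speed_kmh` (`NA` = impassable).
#' @export
scenario_table <- function(scenario, corrected = FALSE) {
  stopifnot(length(scenario) == 1, scenario %in% 1:4)
  mc <- merged_classes()
  tbl <- tibble::tibble(
    class_code = mc$code,
    class_label = mc$label,
    mode = "walking",
    speed_kmh = unname(.walk_speeds[mc$label])
  )
  set <- function(tbl, label, mode, speed) {
    i <- match(label, tbl$class_label)
    tbl$mode[i] <- mode
    tbl$speed_kmh[i] <- speed
    tbl
  }
  if (scenario == 2) {
    tbl <- set(tbl, "MajorRoad", "motorcycle", 40)
    tbl <- set(tbl, "SecondaryRoad", "motorcycle", 25)
    tbl <- set(tbl, "TertiaryAllVehicle", "motorcycle", 15)
    tbl <- set(tbl, "TertiaryTwoWheeler", "motorcycle", 15)
  } else if (scenario == 3) {
    tbl <- set(tbl, "MajorRoad", "public_transport", if (corrected) 40 else 1.25)
    tbl <- set(tbl, "SecondaryRoad", "public_transport", 40)
    tbl <- set(tbl, "TertiaryAllVehicle", "public_transport", 20)
  } else if (scenario == 4) {
    tbl <- set(tbl, "MajorRoad", "private_vehicle", 40)
    tbl <- set(tbl, "SecondaryRoad", "private_vehicle", 35)
    tbl <- set(tbl, "TertiaryAllVehicle", "private_vehicle", 15)
  }
  tbl$mode[is.na(tbl$speed_kmh)] <- NA_character_
  validate_scenario(tbl)
}

#' Validate a travel-scenario table
#'
#' Checks that the table covers all 12 merged classes exactly once, that
#' defined speeds are positive, that water is impassable, and that modes
#' are known.
#'
#' @param scenario A scenario tibble (see [scenario_table()]).
#' @return The validated tibble (invisibly usable in a pipe).
#' @export
validate_scenario <- function(scenario) {
  need <- c("class_code", "class_label", "mode", "speed_kmh")
  if (!all(need %in% names(scenario))) {
    stop("scenario table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  mc <- merged_classes()
  if (!setequal(scenario$class_code, mc$code) ||
      nrow(scenario) != nrow(mc)) {
    stop("scenario table must cover each of the 12 merged classes once",
         call. = FALSE)
  }
  if (any(scenario$speed_kmh <= 0, na.rm = TRUE)) {
    stop("scenario speeds must be positive where defined", call. = FALSE)
  }
  water <- scenario$speed_kmh[scenario$class_label == "Waterbodies"]
  if (!is.na(water)) {
    stop("Waterbodies must be impassable (blank speed)", call. = FALSE)
  }
  known <- c("walking", "motorcycle", "public_transport", "private_vehicle")
  bad <- setdiff(scenario$mode[!is.na(scenario$mode)], known)
  if (length(bad)) {
    stop("unknown travel modes: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  scenario
}

#' Read / write a scenario CSV
#'
#' The on-disk scenario format has exactly the columns `class_label`,
#' `mode`, `speed_kmh`; a blank speed means the class is impassable.
#' Headers are validated strictly.
#'
#' @param path CSV path.
#' @return [read_scenario()]: a validated scenario tibble.
#' @export
read_scenario <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (!identical(hdr, c("class_label", "mode", "speed_kmh"))) {
    stop("scenario CSV must have exactly the header ",
         "'class_label,mode,speed_kmh', got: ",
         paste(hdr, collapse = ","), call. = FALSE)
  }
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      class_label = readr::col_character(),
      mode = readr::col_character(),
      speed_kmh = readr::col_double()
    )
  )
  tbl$class_code <- merged_classes()$code[
    match(tbl$class_label, merged_classes()$label)
  ]
  if (anyNA(tbl$class_code)) {
    stop("unknown class labels in scenario CSV: ",
         paste(tbl$class_label[is.na(tbl$class_code)], collapse = ", "),
         call. = FALSE)
  }
  validate_scenario(dplyr::select(
    tbl, "class_code", "class_label", "mode", "speed_kmh"
  ))
}

#' @rdname read_scenario
#' @param scenario A scenario tibble.
#' @export
write_scenario <- function(scenario, path) {
  validate_scenario(scenario)
  readr::write_csv(
    dplyr::select(scenario, "class_label", "mode", "speed_kmh"),
    path
  )
  invisible(path)
}

#' Write the built-in scenario tables as CSV fixtures
#'
#' Emits `scenario1.csv` ... `scenario4.csv` (verbatim, anomaly included)
#' plus `scenario3_corrected.csv` into a directory.
#'
#' @param dir Output directory (created if missing).
#' @return Character vector of file paths, invisibly.
#' @export
make_fixture_scenarios <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in 1:4) {
    p <- file.path(dir, paste0("scenario", s, ".csv"))
    write_scenario(scenario_table(s), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "scenario3_corrected.csv")
  write_scenario(scenario_table(3, corrected = TRUE), p)
  invisible(c(paths, p))
}

#' Derive the conflict variant of a walking scenario
#'
#' During active conflict, motorized movement stops and walking is slower
#' (detours along ridges): every defined speed of a walking-only scenario
#' is halved; impassable classes stay impassable.
#'
#' @param scenario_walk A walking-only scenario tibble.
#' @return A scenario tibble with halved speeds.
#' @export
conflict_transform <- function(scenario_walk) {
  validate_scenario(scenario_walk)
  motor <- !is.na(scenario_walk$mode) & scenario_walk$mode != "walking"
  if (any(motor)) {
    stop("conflict transform applies to walking-only scenarios; ",
         "motorized classes present: ",
         paste(scenario_walk$class_label[motor], collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(scenario_walk, speed_kmh = .data$speed_kmh / 2)
}

#' Build per-cell speed and walking-mask surfaces
#'
#' Maps each merged land-cover cell to the scenario's flat speed for that
#' class. Barrier/impassable cells and nodata cells become `NA`. The
#' walking mask marks cells whose mode is walking; only those cells
#' receive the Tobler slope correction during travel-time computation —
#' motorized speeds are used as-is.
#'
#' @param merged Merged land-cover [raster_grid()].
#' @param scenario A validated scenario tibble.
#' @return List with elements `speed` (km/h [raster_grid()]) and
#'   `walking_mask` (1/0 [raster_grid()]).
#' @export
build_speed_surface <- function(merged, scenario) {
  validate_scenario(scenario)
  vals <- merged$values
  present <- unique(vals[!is.na(vals)])
  unknown <- setdiff(present, scenario$class_code)
  if (length(unknown)) {
    stop("merged grid contains class codes absent from the scenario: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  pos <- match(as.vector(vals), scenario$class_code)
  speed <- matrix(scenario$speed_kmh[pos], nrow = nrow(vals))
  walking <- matrix(
    as.numeric(!is.na(scenario$mode[pos]) & scenario$mode[pos] == "walking"),
    nrow = nrow(vals)
  )
  walking[is.na(speed)] <- NA_real_
  list(
    speed = raster_grid(speed, merged$origin_x, merged$origin_y,
                        merged$cell_size, crs = merged$crs, nodata = -9999),
    walking_mask = raster_grid(walking, merged$origin_x, merged$origin_y,
                               merged$cell_size, crs = merged$crs,
                               nodata = 255)
  )
}
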