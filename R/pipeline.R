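#' Run the full accessibility and coverage pipeline
#'
#' Executes every stage end-to-end on a generated (or loaded) landscape:
#' land-cover merge, per-scenario speed surfaces, travel-time surfaces
#' per scenario and service package, village travel summaries, proximity
#' tables, barrier-corrected population, capacity-constrained coverage,
#' zonal statistics, and the conflict remodelling (walking-only scenario
#' with halved speeds, summarized over border-flagged villages only).
#'
#' @param config Either a `pipeline_config` list (see
#'   [pipeline_config()]), or a path to a YAML file with the same fields.
#' @return A named list: `landscape`, `merged`, `travel` (tibble of
#'   per-scenario/service summaries with list-columns), `proximity`,
#'   `coverage` (tibble of coverage summaries), `zonal`, `correlation`,
#'   `conflict` (including [report_conflict_delta()] output), and
#'   `manifest`. If `out_dir` is set, rasters/CSVs and a JSON manifest
#'   are written there as a side effect.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  land <- stage("synthetic_landscape", {
    ls_cfg <- do.call(
      landscape_config,
      utils::modifyList(list(seed = config$seed), config$landscape)
    )
    generate_landscape(ls_cfg)
  })

  merged <- stage("landcover_merge", {
    roads_r <- rasterize_lines(land$roads, land$dem)
    rivers_r <- rasterize_lines(land$rivers, land$dem)
    merge_layers(land$landcover, roads_r, rivers_r)
  })
  facilities <- snap_points_off_barriers(land$facilities, merged)

  pop_corr <- stage(
    "population_correction",
    correct_population_off_barriers(land$population, merged)
  )

  scen_tbls <- lapply(config$scenarios, scenario_table)
  names(scen_tbls) <- paste0("scenario", config$scenarios)
  max_time_of <- function(service) {
    if (service == "ambulatory_immunization") config$max_time_ambulatory_h
    else config$max_time_delivery_inpatient_h
  }

  travel <- stage("travel_time", {
    purrr::map_dfr(names(scen_tbls), function(sn) {
      sf <- build_speed_surface(merged, scen_tbls[[sn]])
      purrr::map_dfr(config$services, function(svc) {
        fac <- dplyr::filter(facilities, .data[[svc]])
        surf <- travel_time_toward(fac, sf$speed, sf$walking_mask, land$dem,
                                   scenario_name = sn, service = svc)
        vs <- village_travel_summary(land$villages, surf)
        tibble::tibble(
          scenario = sn, service = svc,
          median_time_h = vs$median_time_h,
          n_unreachable = vs$n_unreachable,
          zone_shares = list(vs$zone_shares),
          villages = list(vs$villages),
          surface = list(surf)
        )
      })
    })
  })

  prox <- stage("proximity",
                proximity_table(land$villages, facilities,
                                config$buffer_specs))

  coverage <- stage("coverage", {
    purrr::map_dfr(names(scen_tbls), function(sn) {
      purrr::map_dfr(config$coverage_services, function(svc) {
        fac <- dplyr::filter(facilities, .data[[svc]])
        cs <- delineate_catchments(fac, merged, land$dem, pop_corr,
                                   scen_tbls[[sn]], max_time_of(svc))
        dplyr::mutate(coverage_summary(cs),
                      scenario = sn, service = svc,
                      catchments = list(cs), .before = 1)
      })
    })
  })

  walk_cov <- dplyr::filter(
    coverage,
    .data$scenario == "scenario1",
    .data$service == config$coverage_services[1]
  )
  zonal <- stage("zonal", {
    if (nrow(walk_cov)) {
      zonal_coverage(walk_cov$catchments[[1]]$served, pop_corr,
                     land$zones, land$zone_names)
    }
  })
  walk_surf <- dplyr::filter(
    travel,
    .data$scenario == "scenario1",
    .data$service == config$services[1]
  )
  correlation <- stage("zonal_correlation", {
    if (nrow(walk_surf)) {
      time_population_correlation(walk_surf$surface[[1]], pop_corr,
                                  land$zones, zone_names = land$zone_names)
    }
  })

  conflict <- stage("conflict", {
    conf_scen <- conflict_transform(scenario_table(1))
    sfc <- build_speed_surface(merged, conf_scen)
    border <- dplyr::filter(land$villages, .data$border)
    purrr::map_dfr(config$services, function(svc) {
      fac <- dplyr::filter(facilities, .data[[svc]])
      surf_c <- travel_time_toward(fac, sfc$speed, sfc$walking_mask,
                                   land$dem, "conflict_walking", svc)
      normal <- dplyr::filter(
        travel, .data$scenario == "scenario1", .data$service == svc
      )$villages[[1]]
      vs_c <- village_travel_summary(border, surf_c)
      delta <- report_conflict_delta(
        dplyr::semi_join(normal, border, by = "village_id"),
        vs_c$villages
      )
      dplyr::mutate(delta, service = svc, .before = 1)
    })
  })

  out <- list(
    landscape = land, merged = merged, population_corrected = pop_corr,
    facilities = facilities,
    travel = travel, proximity = prox, coverage = coverage,
    zonal = zonal, correlation = correlation, conflict = conflict
  )
  if (!is.null(config$out_dir)) {
    out$manifest <- write_pipeline_outputs(out, config)
  }
  out
}

#' Pipeline configuration
#'
#' @param seed Integer seed for the synthetic landscape.
#' @param landscape Named list of overrides for [landscape_config()].
#' @param scenarios Scenario numbers to run (subset of 1:4).
#' @param services Service packages for travel-time analysis.
#' @param coverage_services Service packages for coverage analysis.
#' @param max_time_ambulatory_h,max_time_delivery_inpatient_h Maximum
#'   travel times (hours) bounding catchments: 1 h for
#'   ambulatory/immunization, 2 h for delivery and inpatient care.
#' @param buffer_specs Proximity radii ([default_buffer_specs()]).
#' @param out_dir Optional output directory; when set, all rasters and
#'   tables are written there with a JSON run manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            landscape = list(),
                            scenarios = 1:4,
                            services = c("ambulatory_immunization",
                                         "delivery", "inpatient"),
                            coverage_services = "ambulatory_immunization",
                            max_time_ambulatory_h = 1,
                            max_time_delivery_inpatient_h = 2,
                            buffer_specs = default_buffer_specs(),
                            out_dir = NULL) {
  known_svc <- c("ambulatory_immunization", "delivery", "inpatient")
  stopifnot(all(scenarios %in% 1:4), all(services %in% known_svc),
            all(coverage_services %in% known_svc),
            max_time_ambulatory_h > 0, max_time_delivery_inpatient_h > 0)
  structure(
    list(
      seed = as.integer(seed), landscape = landscape,
      scenarios = scenarios, services = services,
      coverage_services = coverage_services,
      max_time_ambulatory_h = max_time_ambulatory_h,
      max_time_delivery_inpatient_h = max_time_delivery_inpatient_h,
      buffer_specs = buffer_specs, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

write_pipeline_outputs <- function(out, config) {
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_landscape(out$landscape, file.path(dir, "inputs"))
  write_raster(out$merged, file.path(dir, "merged_landcover.asc"))
  write_raster(out$population_corrected,
               file.path(dir, "population_corrected.asc"))
  for (i in seq_len(nrow(out$travel))) {
    nm <- paste0("traveltime_", out$travel$scenario[i], "_",
                 out$travel$service[i])
    write_raster(out$travel$surface[[i]]$time,
                 file.path(dir, paste0(nm, ".asc")))
  }
  readr::write_csv(
    dplyr::select(out$travel, -dplyr::where(is.list)),
    file.path(dir, "travel_summary.csv")
  )
  readr::write_csv(out$proximity, file.path(dir, "proximity.csv"))
  readr::write_csv(
    dplyr::select(out$coverage, -dplyr::where(is.list)),
    file.path(dir, "coverage_summary.csv")
  )
  if (!is.null(out$zonal)) {
    readr::write_csv(out$zonal, file.path(dir, "zonal_coverage.csv"))
  }
  readr::write_csv(out$conflict, file.path(dir, "conflict_delta.csv"))
  manifest <- list(
    seed = config$seed,
    scenarios = config$scenarios,
    services = config$services,
    max_time_h = c(ambulatory_immunization = config$max_time_ambulatory_h,
                   delivery_inpatient = config$max_time_delivery_inpatient_h),
    files = list.files(dir, recursive = TRUE)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Compare village access under normal and conflict regimes
#'
#' Tabulates, for the same set of (border) villages, the share within one
#' hour of care under each regime and the ratio of median travel times.
#'
#' @param normal Per-village tibble (with `village_id`, `time_h`) under
#'   the normal walking scenario.
#' @param conflict Same villages under the conflict scenario.
#' @return One-row tibble: `pct_within_1h_normal`,
#'   `pct_within_1h_conflict`, `median_normal_h`, `median_conflict_h`,
#'   `median_ratio`.
#' @export
report_conflict_delta <- function(normal, conflict) {
  stopifnot(all(c("village_id", "time_h") %in% names(normal)),
            all(c("village_id", "time_h") %in% names(conflict)))
  if (!setequal(normal$village_id, conflict$village_id)) {
    stop("normal and conflict summaries cover different villages",
         call. = FALSE)
  }
  conflict <- conflict[match(normal$village_id, conflict$village_id), ]
  pct1 <- function(t) 100 * mean(!is.na(t) & t <= 1)
  mn <- stats::median(normal$time_h, na.rm = TRUE)
  mc <- stats::median(conflict$time_h, na.rm = TRUE)
  tibble::tibble(
    n_villages = nrow(normal),
    pct_within_1h_normal = pct1(normal$time_h),
    pct_within_1h_conflict = pct1(conflict$time_h),
    median_normal_h = mn,
    median_conflict_h = mc,
    median_ratio = mc / mn
  )
}
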