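#' Pipeline run configuration
#'
#' Validates paths and analysis settings for [run_pipeline()]. Wave labels
#' must be strictly increasing when numeric; referenced input paths must
#' exist at validation time.
#'
#' @param settlements Path to the settlement CSV (required).
#' @param out_dir Output directory (required; created on run).
#' @param dem Optional ESRI ASCII DEM path.
#' @param road_edges,road_nodes Optional road-graph CSV paths (or a single
#'   GeoJSON in `road_edges`).
#' @param benchmark_observed Optional observed regional benchmark CSV.
#' @param waves Census wave labels in chronological order; `NULL` uses all
#'   `pop_` columns in file order.
#' @param distance_kind `"euclidean"` or `"network"` (requires roads).
#' @param grid A [grid_spec()].
#' @param coords Coordinate convention of the settlement CSV.
#' @param tri_radius_km Buffer radius for settlement TRI averaging.
#' @param flow_threshold Strict threshold for exported flow-network edges.
#' @param rd_mode Relative-difference zero handling: `"marker"` or
#'   `"epsilon"`.
#' @param epsilon Stabiliser for `rd_mode = "epsilon"`.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(settlements, out_dir,
                            dem = NULL, road_edges = NULL, road_nodes = NULL,
                            benchmark_observed = NULL, waves = NULL,
                            distance_kind = c("euclidean", "network"),
                            grid = grid_spec(), coords = "planar_km",
                            tri_radius_km = 2, flow_threshold = 1,
                            rd_mode = c("marker", "epsilon"), epsilon = 1e-9,
                            seed = 1L) {
  distance_kind <- match.arg(distance_kind)
  rd_mode <- match.arg(rd_mode)
  for (p in c(settlements, dem, road_edges, road_nodes, benchmark_observed)) {
    if (!file.exists(p)) abort_field("paths", paste("file not found:", p))
  }
  if (distance_kind == "network" && is.null(road_edges)) {
    abort_field("distance_kind", "network distances require a road graph")
  }
  if (!is.null(waves)) {
    wn <- suppressWarnings(as.numeric(waves))
    if (!anyNA(wn) && any(diff(wn) <= 0)) {
      abort_field("waves", "wave labels must be strictly increasing")
    }
  }
  structure(
    list(
      settlements = settlements, out_dir = out_dir, dem = dem,
      road_edges = road_edges, road_nodes = road_nodes,
      benchmark_observed = benchmark_observed, waves = waves,
      distance_kind = distance_kind, grid = grid, coords = coords,
      tri_radius_km = tri_radius_km, flow_threshold = flow_threshold,
      rd_mode = rd_mode, epsilon = epsilon, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments
#'   (grid given as `gamma`, `beta`, `families`, `objective` sub-keys).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$grid)) y$grid <- do.call(grid_spec, y$grid)
  do.call(pipeline_config, y)
}

#' Run the full migration-modelling pipeline
#'
#' Executes distances, terrain (if a DEM is configured), and per
#' intercensal interval the target derivation, grid-search calibration,
#' flow prediction, validation and reporting stages, writing every
#' artefact plus a reproducibility manifest (input hashes, config, seed,
#' package version, per-stage log) to the output directory. A stage
#' failure aborts with the stage name. Idempotent for fixed inputs and
#' seed.
#'
#' @param config A `run_config` from [pipeline_config()] or
#'   [read_run_config()], or a YAML path.
#' @return Invisibly, a list with the manifest and the per-interval
#'   calibration results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  stage <- function(name, code) {
    t0 <- Sys.time()
    res <- tryCatch(force(code), error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
        class = "gravityflow_stage_error"
      )
    })
    log[[name]] <<- list(
      stage = name,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    res
  }

  settlements <- stage("read", read_settlements(config$settlements, coords = config$coords))
  waves <- config$waves %||% wave_labels(settlements)
  if (length(waves) < 2) abort_field("waves", "need at least two census waves")

  euclid <- stage("distances", euclidean_matrix(settlements))
  network <- NULL
  if (!is.null(config$road_edges)) {
    network <- stage("network_distances", {
      graph <- read_road_graph(config$road_edges, config$road_nodes)
      nm <- network_matrix(settlements, graph)
      el <- elongation_summary(euclid, nm)
      readr::write_csv(el$summary, file.path(config$out_dir, "elongation_summary.csv"))
      nm
    })
  }
  distances <- if (config$distance_kind == "network") network else euclid

  ruggedness <- NULL
  if (!is.null(config$dem)) {
    ruggedness <- stage("terrain", {
      dem <- read_dem_ascii(config$dem)
      rt <- ruggedness_table(tri(dem), settlements, radius_km = config$tri_radius_km)
      readr::write_csv(rt, file.path(config$out_dir, "ruggedness.csv"))
      rt
    })
  }

  calibrations <- list()
  summaries <- list()
  for (w in seq_len(length(waves) - 1)) {
    iv <- c(waves[w], waves[w + 1])
    label <- paste(iv, collapse = "-")
    cal <- stage(paste0("calibrate_", label),
      grid_search(settlements, distances, iv[1], iv[2], grid = config$grid)
    )
    calibrations[[label]] <- cal
    stage(paste0("predict_", label), {
      readr::write_csv(
        tibble::as_tibble(cal),
        file.path(config$out_dir, sprintf("calibration_%s.csv", label))
      )
      params <- best_params(cal)
      flows <- predict_flows(settlements, distances, params, wave = iv[1], interval = iv)
      s <- flow_summary(flows)
      s$interval <- label
      summaries[[label]] <- s
      readr::write_csv(s, file.path(config$out_dir, sprintf("migration_summary_%s.csv", label)))
      targets <- attr(cal, "targets")
      proj <- project_population(settlements, targets$growth_factor, s, wave = iv[1])
      readr::write_csv(proj, file.path(config$out_dir, sprintf("projected_pop_%s.csv", label)))
      net <- export_flow_network(flows, settlements, threshold = config$flow_threshold)
      write_flow_network(net,
        graphml_path = file.path(config$out_dir, sprintf("flow_network_%s.graphml", label)),
        nodes_path = file.path(config$out_dir, sprintf("flow_nodes_%s.csv", label)),
        edges_path = file.path(config$out_dir, sprintf("flow_edges_%s.csv", label))
      )
      if (!is.null(ruggedness)) {
        stats_tbl <- tri_migration_stats(ruggedness, setNames(list(s), label))
        readr::write_csv(stats_tbl, file.path(config$out_dir, sprintf("tri_stats_%s.csv", label)))
        td <- top_destinations(flows, ruggedness)
        readr::write_csv(td, file.path(config$out_dir, sprintf("top_destinations_%s.csv", label)))
      }
      if (!is.null(config$benchmark_observed)) {
        obs <- read_regional_matrix(config$benchmark_observed)
        pred <- aggregate_regions(flows, settlements)
        pred <- pred[rownames(obs), colnames(obs), drop = FALSE]
        rc <- regional_comparison(pred, obs,
          mode = config$rd_mode, epsilon = config$epsilon
        )
        write_regional_comparison(
          rc, file.path(config$out_dir, sprintf("regional_benchmark_%s.csv", label))
        )
      }
      NULL
    })
  }

  stage("distributions", {
    dist_tbl <- flow_distributions(summaries)
    readr::write_csv(dist_tbl$skewness, file.path(config$out_dir, "flow_skewness.csv"))
    readr::write_csv(dist_tbl$log_bins, file.path(config$out_dir, "flow_log_bins.csv"))
  })

  manifest <- list(
    package = "gravityflow",
    version = as.character(utils::packageVersion("gravityflow")),
    seed = config$seed,
    inputs = lapply(
      Filter(Negate(is.null), config[c(
        "settlements", "dem", "road_edges", "road_nodes", "benchmark_observed"
      )]),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))
    ),
    config = list(
      waves = waves, distance_kind = config$distance_kind,
      gamma = config$grid$gamma, beta = config$grid$beta,
      families = config$grid$families, objective = config$grid$objective,
      tri_radius_km = config$tri_radius_km,
      flow_threshold = config$flow_threshold, rd_mode = config$rd_mode
    ),
    best = lapply(calibrations, function(cal) as.list(glance(cal))),
    stages = unname(log)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(list(manifest = manifest, calibrations = calibrations))
}
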