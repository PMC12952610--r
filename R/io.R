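# Readers and writers for the on-disk formats: settlement CSV, long-format
# flow CSV, ESRI ASCII grid DEMs, road-graph CSV/GeoJSON, flow-network
# GraphML + CSV, regional-comparison panels.

#' Read a settlement table
#'
#' Expects a CSV with header `id, name, x, y, region, pop_<wave>...`.
#' Ids must be unique and populations nonnegative integers; violations are
#' validation errors reporting the offending ids / row numbers.
#'
#' @param path CSV path.
#' @param coords Coordinate convention of `x`/`y`: `"planar_km"` or
#'   `"lonlat"`; a `coords` column-free header flag is not used, the
#'   convention travels with the call or config.
#' @return A settlement tibble with the `coords` attribute set.
#' @export
read_settlements <- function(path, coords = c("planar_km", "lonlat")) {
  coords <- match.arg(coords)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("id", "name", "x", "y", "region")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort_field("settlements", paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  df$id <- as.character(df$id)
  pops <- pop_columns(df)
  if (length(pops) == 0) abort_field("settlements", "no pop_<wave> columns found")
  if (anyDuplicated(df$id)) {
    rows <- which(duplicated(df$id) | duplicated(df$id, fromLast = TRUE))
    abort_field("id", sprintf(
      "duplicated ids %s (rows %s)",
      paste(unique(df$id[rows]), collapse = ", "),
      paste(rows, collapse = ", ")
    ))
  }
  for (p in pops) {
    bad <- which(is.na(df[[p]]) | df[[p]] < 0 | df[[p]] != floor(df[[p]]))
    if (length(bad) > 0) {
      abort_field(p, sprintf(
        "populations must be nonnegative integers (rows %s)",
        paste(head(bad, 10), collapse = ", ")
      ))
    }
    df[[p]] <- as.integer(df[[p]])
  }
  attr(df, "coords") <- coords
  df
}

#' Write a settlement table
#'
#' @param settlements Settlement tibble.
#' @param path CSV destination.
#' @return The path, invisibly.
#' @export
write_settlements <- function(settlements, path) {
  readr::write_csv(settlements, path)
  invisible(path)
}

#' Read flows from long-format CSV
#'
#' @param path CSV with columns `origin`, `destination`, `flow`.
#' @param ids Full settlement id set; absent pairs become zero flows.
#' @param interval Optional interval labels.
#' @return A [flow_matrix()].
#' @export
read_flows <- function(path, ids = NULL, interval = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          origin = readr::col_character(),
                          destination = readr::col_character(),
                          flow = readr::col_double()
                        ))
  long_to_flows(df, ids = ids, interval = interval)
}

#' Write flows as long-format CSV
#'
#' Long format (origin, destination, flow) avoids n x n text blow-ups for
#' large settlement systems; zero flows are dropped.
#'
#' @param flows A [flow_matrix()].
#' @param path CSV destination.
#' @return The path, invisibly.
#' @export
write_flows <- function(flows, path) {
  readr::write_csv(flows_to_long(flows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid DEM
#'
#' Header keys `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize` and
#' optional `NODATA_value` are handled exactly. Corner coordinates and
#' `cellsize` are in the planar-km convention; elevations in metres.
#'
#' @param path ASCII grid path.
#' @return A [dem_grid()].
#' @export
read_dem_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  n_hdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && tolower(parts[1]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1
    } else {
      break
    }
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr))) {
    abort_field("path", paste("ESRI ASCII header incomplete; need", paste(req, collapse = ", ")))
  }
  vals <- scan(text = paste(lines[-seq_len(n_hdr)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    abort_field("path", sprintf(
      "expected %d values, found %d", hdr$ncols * hdr$nrows, length(vals)
    ))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA_real_
  dem_grid(m,
    cellsize_m = hdr$cellsize * 1000,
    xll = hdr$xllcorner, yll = hdr$yllcorner, nodata = nodata
  )
}

#' Write a DEM as ESRI ASCII grid
#'
#' @param dem A [dem_grid()].
#' @param path Destination path.
#' @param digits Significant digits written (default 10).
#' @return The path, invisibly.
#' @export
write_dem_ascii <- function(dem, path, digits = 10) {
  m <- dem$elev
  m[is.na(m)] <- dem$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", dem$xll),
    sprintf("yllcorner %.10g", dem$yll),
    sprintf("cellsize %.10g", dem$cellsize_m / 1000),
    sprintf("NODATA_value %.10g", dem$nodata)
  )
  body <- apply(m, 1, function(r) paste(formatC(r, format = "g", digits = digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a road graph
#'
#' Either a pair of CSVs (edges with `from,to,length_km` -- `u,v` accepted
#' as synonyms -- and nodes with `id,x,y`) or a GeoJSON file of LineString
#' features carrying a `length_km` property, from which nodes are derived
#' at the segment endpoints.
#'
#' @param edges_path Edge-list CSV or GeoJSON path.
#' @param nodes_path Node CSV path (ignored for GeoJSON).
#' @return A [road_graph()].
#' @export
read_road_graph <- function(edges_path, nodes_path = NULL) {
  if (grepl("\\.geojson$", edges_path, ignore.case = TRUE)) {
    return(read_road_geojson(edges_path))
  }
  if (is.null(nodes_path)) abort_field("nodes_path", "required for CSV road graphs")
  edges <- readr::read_csv(edges_path, show_col_types = FALSE, progress = FALSE)
  nodes <- readr::read_csv(nodes_path, show_col_types = FALSE, progress = FALSE)
  if (all(c("u", "v") %in% names(edges))) {
    edges <- dplyr::rename(edges, from = "u", to = "v")
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  nodes$id <- as.character(nodes$id)
  road_graph(nodes, edges)
}

read_road_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% abort_field("path", "GeoJSON has no features")
  seen <- character(0)
  node_x <- numeric(0)
  node_y <- numeric(0)
  node_id <- function(x, y) {
    key <- sprintf("%.9g_%.9g", x, y)
    i <- match(key, seen)
    if (is.na(i)) {
      seen <<- c(seen, key)
      node_x <<- c(node_x, x)
      node_y <<- c(node_y, y)
      i <- length(seen)
    }
    sprintf("N%d", i)
  }
  edges <- purrr::map_dfr(feats, function(f) {
    if (!identical(f$geometry$type, "LineString")) return(NULL)
    cc <- f$geometry$coordinates
    a <- cc[[1]]
    b <- cc[[length(cc)]]
    len <- f$properties$length_km %||% f$properties$length
    if (is.null(len)) abort_field("path", "LineString feature without a length property")
    tibble::tibble(
      from = node_id(a[[1]], a[[2]]),
      to = node_id(b[[1]], b[[2]]),
      length_km = as.numeric(len)
    )
  })
  road_graph(
    nodes = tibble::tibble(id = sprintf("N%d", seq_along(seen)), x = node_x, y = node_y),
    edges = edges
  )
}

#' Write a road graph as node and edge CSVs
#'
#' @param graph A [road_graph()].
#' @param edges_path,nodes_path Destination CSV paths.
#' @return The edge path, invisibly.
#' @export
write_road_graph <- function(graph, edges_path, nodes_path) {
  readr::write_csv(graph$edges, edges_path)
  readr::write_csv(graph$nodes, nodes_path)
  invisible(edges_path)
}

#' Write a flow network as GraphML and CSVs
#'
#' @param network A `flow_network` from [export_flow_network()].
#' @param graphml_path Optional GraphML destination.
#' @param nodes_path,edges_path Optional CSV destinations.
#' @return Invisibly, the paths written.
#' @export
write_flow_network <- function(network, graphml_path = NULL,
                               nodes_path = NULL, edges_path = NULL) {
  written <- character(0)
  if (!is.null(graphml_path)) {
    ig <- igraph::graph_from_data_frame(
      network$edges,
      directed = TRUE,
      vertices = network$nodes
    )
    igraph::write_graph(ig, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(nodes_path)) {
    readr::write_csv(network$nodes, nodes_path)
    written <- c(written, nodes_path)
  }
  if (!is.null(edges_path)) {
    readr::write_csv(network$edges, edges_path)
    written <- c(written, edges_path)
  }
  invisible(written)
}

#' Read a regional benchmark matrix
#'
#' CSV with a leading `region` column and one numeric column per
#' destination region. An optional `Total` row/column is kept apart and
#' returned as attribute `totals`.
#'
#' @param path CSV path.
#' @return Numeric R x R matrix with region dimnames; printed totals (if
#'   present) in `attr(, "totals")` as `list(row, col, grand)`.
#' @export
read_regional_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  labs <- as.character(df[[1]])
  m <- as.matrix(df[-1])
  rownames(m) <- labs
  totals <- NULL
  if ("Total" %in% labs || "Total" %in% colnames(m)) {
    has_rt <- "Total" %in% colnames(m)
    has_ct <- "Total" %in% labs
    core <- m[setdiff(labs, "Total"), setdiff(colnames(m), "Total"), drop = FALSE]
    totals <- list(
      row = if (has_rt) m[setdiff(labs, "Total"), "Total"] else NULL,
      col = if (has_ct) m["Total", setdiff(colnames(m), "Total")] else NULL,
      grand = if (has_rt && has_ct) m["Total", "Total"] else NULL
    )
    m <- core
  }
  attr(m, "totals") <- totals
  m
}

#' Write a regional comparison as stacked CSV panels
#'
#' Emits three stacked panels (predicted, observed, relative difference)
#' with label rows/columns and totals; undefined relative differences print
#' as a dash.
#'
#' @param comparison A `regional_comparison`.
#' @param path Destination path.
#' @param digits Rounding for the relative-difference panel (default 2).
#' @return The path, invisibly.
#' @export
write_regional_comparison <- function(comparison, path, digits = 2) {
  panel <- function(m, title, fmt) {
    rows <- apply(m, 1, function(r) paste(fmt(r), collapse = ","))
    c(title, paste0("region,", paste(colnames(m), collapse = ",")),
      paste(rownames(m), rows, sep = ","), "")
  }
  rd_fmt <- function(r) {
    out <- formatC(round(r, digits), format = "f", digits = digits)
    out[is.na(r)] <- "-"
    out
  }
  lines <- c(
    panel(comparison$predicted, "Predicted flows", function(r) format(r, trim = TRUE)),
    panel(comparison$observed, "Observed flows", function(r) format(r, trim = TRUE)),
    panel(comparison$rd, "Relative difference", rd_fmt)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a full synthetic world to disk
#'
#' Settlement CSV, ESRI ASCII DEM, road-graph CSVs, long-format flow CSV
#' and a provenance YAML (config fields + seed).
#'
#' @param world A `synthetic_world` from [generate_world()].
#' @param dir Output directory (created if needed).
#' @param config The [synthetic_config()] that produced the world.
#' @return Invisibly, the directory.
#' @export
write_world <- function(world, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_settlements(world$settlements, file.path(dir, "settlements.csv"))
  if (!is.null(world$dem)) write_dem_ascii(world$dem, file.path(dir, "dem.asc"))
  if (!is.null(world$roads)) {
    write_road_graph(world$roads, file.path(dir, "road_edges.csv"),
                     file.path(dir, "road_nodes.csv"))
  }
  write_flows(world$flows, file.path(dir, "flows.csv"))
  prov <- config
  prov$true_params <- unclass(prov$true_params)
  prov$bbox <- as.numeric(prov$bbox)
  yaml::write_yaml(unclass(prov), file.path(dir, "provenance.yml"))
  invisible(dir)
}
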