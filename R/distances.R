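#' Distance matrix constructor
#'
#' A symmetric settlement-to-settlement separation matrix in kilometres with
#' a zero diagonal. Off-diagonal zeros (duplicate coordinates) and
#' non-finite entries are validation errors: unreachable pairs must be
#' resolved upstream, never encoded as infinities.
#'
#' @param values Square numeric matrix of separations in km, dimnames set to
#'   settlement ids.
#' @param kind `"euclidean"` or `"network"`.
#' @param coords Coordinate convention the matrix was built from.
#' @return The matrix with class `dist_matrix` and `kind`/`coords`
#'   attributes.
#' @export
dist_matrix <- function(values, kind = c("euclidean", "network"),
                        coords = "planar_km") {
  kind <- match.arg(kind)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    abort_field("values", "must be a square matrix")
  }
  if (is.null(rownames(values))) abort_field("values", "must carry settlement ids as dimnames")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-9))) {
    abort_field("values", "must be symmetric")
  }
  if (any(!is.finite(values))) abort_field("values", "must be finite (no unreachable pairs)")
  if (any(diag(values) != 0)) abort_field("values", "diagonal must be zero")
  off <- values[row(values) != col(values)]
  if (any(off <= 0)) {
    idx <- which(values <= 0 & row(values) != col(values), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pairs <- paste(rownames(values)[idx[, 1]], rownames(values)[idx[, 2]], sep = "-")
    abort_field("values", paste(
      "zero or negative off-diagonal distance for pairs:",
      paste(head(pairs, 5), collapse = ", ")
    ))
  }
  structure(values, class = c("dist_matrix", "matrix"), kind = kind, coords = coords)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf(
    "<dist_matrix> %s, %d settlements, %s coordinates\n",
    attr(x, "kind"), nrow(x), attr(x, "coords")
  ))
  invisible(x)
}

#' Euclidean (or great-circle) distance matrix
#'
#' Planar-km coordinates give straight-line distances; lon/lat coordinates
#' give great-circle distances by the haversine formula with Earth radius
#' 6371 km. Duplicate coordinates for distinct settlements are a validation
#' error (they would produce a zero off-diagonal distance).
#'
#' @param settlements Settlement table with `id`, `x`, `y`.
#' @param coords `"planar_km"` or `"lonlat"`; defaults to the table's
#'   `coords` attribute.
#' @return A [dist_matrix()] of kind `"euclidean"`.
#' @export
#' @examples
#' st <- tibble::tibble(id = c("A", "B"), x = c(0, 3), y = c(0, 4))
#' euclidean_matrix(st)["A", "B"] # 5 km
euclidean_matrix <- function(settlements, coords = NULL) {
  validate_settlements(settlements)
  coords <- settlement_coords(settlements, coords)
  xy <- cbind(settlements$x, settlements$y)
  m <- if (coords == "planar_km") {
    as.matrix(stats::dist(xy))
  } else {
    geosphere::distm(xy, fun = function(p1, p2) {
      geosphere::distHaversine(p1, p2, r = 6371000)
    }) / 1000
  }
  dup <- which(m == 0 & row(m) != col(m), arr.ind = TRUE)
  if (nrow(dup) > 0) {
    dup <- dup[dup[, 1] < dup[, 2], , drop = FALSE]
    pairs <- paste(settlements$id[dup[, 1]], settlements$id[dup[, 2]], sep = "-")
    abort_field("settlements", paste(
      "duplicate coordinates for distinct settlements:",
      paste(head(pairs, 5), collapse = ", ")
    ))
  }
  dimnames(m) <- list(settlements$id, settlements$id)
  dist_matrix(m, kind = "euclidean", coords = coords)
}

#' Road graph constructor
#'
#' @param nodes Tibble with `id`, `x`, `y` (same coordinate convention as
#'   the settlements the graph will serve).
#' @param edges Tibble with `from`, `to`, `length_km`; undirected, no
#'   self-loops, positive lengths.
#' @return A list of class `road_graph`.
#' @export
road_graph <- function(nodes, edges) {
  if (anyDuplicated(nodes$id)) abort_field("nodes", "node ids must be unique")
  if (any(edges$length_km <= 0)) abort_field("edges", "edge lengths must be > 0")
  if (any(edges$from == edges$to)) abort_field("edges", "self-loop edges are not allowed")
  missing_nodes <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing_nodes) > 0) {
    abort_field("edges", paste("edge endpoints missing from nodes:",
                               paste(head(missing_nodes, 5), collapse = ", ")))
  }
  structure(
    list(
      nodes = tibble::as_tibble(nodes[c("id", "x", "y")]),
      edges = tibble::as_tibble(edges[c("from", "to", "length_km")])
    ),
    class = "road_graph"
  )
}

#' @export
print.road_graph <- function(x, ...) {
  cat(sprintf("<road_graph> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Road-network distance matrix
#'
#' Each settlement is snapped to its single nearest graph node by a straight
#' connector of Euclidean length (zero when the settlement sits on a node);
#' the network distance between two settlements is then connector + shortest
#' path over the road graph + connector. Settlements snapping to the same
#' node are joined through that node. Any unreachable pair is an error
#' reporting the graph components involved.
#'
#' @param settlements Settlement table with planar-km coordinates.
#' @param graph A [road_graph()].
#' @return A [dist_matrix()] of kind `"network"`.
#' @export
network_matrix <- function(settlements, graph) {
  validate_settlements(settlements)
  if (nrow(graph$edges) == 0) abort_field("graph", "road graph has no edges")
  ig <- igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = graph$nodes
  )
  comp <- igraph::components(ig)
  # nearest-node snapping
  d2 <- outer(settlements$x, graph$nodes$x, "-")^2 +
    outer(settlements$y, graph$nodes$y, "-")^2
  snap <- apply(d2, 1, which.min)
  conn <- sqrt(d2[cbind(seq_len(nrow(settlements)), snap)])
  snap_id <- graph$nodes$id[snap]
  snap_comp <- comp$membership[snap_id]
  if (length(unique(snap_comp)) > 1) {
    abort(sprintf(
      "road graph disconnected across snap targets: settlements attach to components %s",
      paste(sort(unique(snap_comp)), collapse = ", ")
    ), class = "gravityflow_validation_error")
  }
  node_d <- igraph::distances(ig,
    v = unique(snap_id), to = unique(snap_id),
    weights = igraph::E(ig)$length_km
  )
  core <- node_d[match(snap_id, rownames(node_d)), match(snap_id, colnames(node_d))]
  m <- outer(conn, conn, "+") + core
  diag(m) <- 0
  dimnames(m) <- list(settlements$id, settlements$id)
  dist_matrix(m, kind = "network", coords = settlement_coords(settlements))
}

#' Compare network against Euclidean separations
#'
#' Per-pair elongation ratios (network / Euclidean) for every unordered
#' off-diagonal pair, with summary statistics. On any road network whose
#' edges are at least as long as their straight-line chords every ratio is
#' at least 1; ratios below 1 are flagged as a data-quality warning.
#'
#' @param euclid,network Two [dist_matrix()] objects over the same
#'   settlement ordering.
#' @return A list with `pairs` (tibble: origin, destination, euclid_km,
#'   network_km, ratio) and `summary` (tibble: min, median, mean, max,
#'   n_below_1).
#' @export
elongation_summary <- function(euclid, network) {
  if (!identical(rownames(euclid), rownames(network))) {
    abort("euclid and network matrices must share the same settlement ordering",
      class = "gravityflow_validation_error"
    )
  }
  idx <- which(upper.tri(euclid), arr.ind = TRUE)
  pairs <- tibble::tibble(
    origin = rownames(euclid)[idx[, 1]],
    destination = rownames(euclid)[idx[, 2]],
    euclid_km = euclid[idx],
    network_km = network[idx],
    ratio = network[idx] / euclid[idx]
  )
  n_below <- sum(pairs$ratio < 1 - 1e-12)
  if (n_below > 0) {
    warn(sprintf("%d pair(s) have network distance below Euclidean distance", n_below))
  }
  list(
    pairs = pairs,
    summary = tibble::tibble(
      min = min(pairs$ratio), median = median(pairs$ratio),
      mean = mean(pairs$ratio), max = max(pairs$ratio),
      n_below_1 = n_below
    )
  )
}

#' Distance matrix in long format
#'
#' @param d A [dist_matrix()].
#' @return Tibble with `origin`, `destination`, `km` for every ordered pair
#'   of distinct settlements.
#' @export
dist_to_long <- function(d) {
  ids <- rownames(d)
  idx <- which(row(d) != col(d), arr.ind = TRUE)
  tibble::tibble(
    origin = ids[idx[, 1]],
    destination = ids[idx[, 2]],
    km = d[idx]
  ) |> dplyr::arrange(.data$origin, .data$destination)
}
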