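#' Configuration for a synthetic settlement system
#'
#' Bundles every knob of the synthetic world: settlement counts and rank-size
#' populations, the bounding box, terrain-ridge parameters for the DEM, the
#' per-edge road detour distribution, the ground-truth gravity parameters and
#' the demographic rates that drive one intercensal interval. Defaults emulate
#' a mid-sized national settlement system observed at decadal censuses: a few
#' hundred settlements with a Zipf population hierarchy, a country-scale
#' bounding box, gross mobility of 5% of the start population over the
#' interval, and uniform natural growth of 5%.
#'
#' @param n_settlements Number of settlements (>= 1).
#' @param n_regions Number of macro-regions settlements are assigned to.
#' @param rank_size_exponent Rank-size (Zipf) slope `s`; population of the
#'   r-th settlement is `round(top_population * r^-s)`.
#' @param top_population Population of the rank-1 settlement.
#' @param bbox Bounding box in planar km, `c(xmin, ymin, xmax, ymax)`.
#' @param n_clusters Number of Gaussian coordinate clusters (0 = uniform only).
#' @param cluster_sd_km Spread of each coordinate cluster in km.
#' @param cluster_fraction Share of settlements drawn from clusters rather
#'   than the uniform background.
#' @param dem List of DEM parameters: `cellsize_m`, optional `nrow`/`ncol`
#'   (derived from the bbox when `NULL`), `n_ridges`, `ridge_amplitude_m`,
#'   `ridge_length_km`, `ridge_width_km`, `noise_sd_m`, `noise_smooth_cells`.
#' @param road_detour List with `meanlog` and `sdlog` of the lognormal
#'   per-edge detour factor; draws are truncated below at 1 so every road
#'   edge is at least as long as its straight-line chord.
#' @param true_params Ground-truth gravity parameters, a [model_params()].
#' @param mobility_rate Fraction `m` of the start population that migrates
#'   over the interval (gross volume `T = m * sum(start)`).
#' @param growth_factor Uniform natural-growth ratio `g` of national end to
#'   start population.
#' @param interval Character vector of the two census wave labels.
#' @param seed Master RNG seed; split internally into named substreams
#'   (settlements / dem / roads / flows) so regenerating one layer leaves the
#'   others untouched.
#'
#' @return A list of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_settlements = 50, seed = 7)
#' cfg$true_params
synthetic_config <- function(n_settlements = 200,
                             n_regions = 7,
                             rank_size_exponent = 1.0,
                             top_population = 50000,
                             bbox = c(xmin = 0, ymin = 0, xmax = 300, ymax = 200),
                             n_clusters = 5,
                             cluster_sd_km = 10,
                             cluster_fraction = 0.6,
                             dem = list(),
                             road_detour = list(meanlog = log(1.25), sdlog = 0.1),
                             true_params = model_params("power", beta = 1.0, gamma = 1.5),
                             mobility_rate = 0.05,
                             growth_factor = 1.05,
                             interval = c("t0", "t1"),
                             seed = 1L) {
  check_positive_count(n_settlements, "n_settlements")
  check_positive_count(n_regions, "n_regions")
  if (rank_size_exponent <= 0) abort_field("rank_size_exponent", "must be > 0")
  check_positive_count(top_population, "top_population")
  if (length(bbox) != 4 || bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    abort_field("bbox", "must be c(xmin, ymin, xmax, ymax) with positive extent")
  }
  if (n_clusters < 0) abort_field("n_clusters", "must be >= 0")
  if (mobility_rate < 0 || mobility_rate >= 1) abort_field("mobility_rate", "must be in [0, 1)")
  if (growth_factor <= 0) abort_field("growth_factor", "must be > 0")
  if (round(top_population * n_settlements^(-rank_size_exponent)) < 1) {
    abort_field("top_population", "too small: the rank-size rule would assign zero population")
  }
  dem_defaults <- list(
    cellsize_m = 1000, nrow = NULL, ncol = NULL,
    n_ridges = 3, ridge_amplitude_m = 1500, ridge_length_km = 120,
    ridge_width_km = 15, noise_sd_m = 40, noise_smooth_cells = 3
  )
  dem <- utils::modifyList(dem_defaults, dem)
  if (dem$cellsize_m <= 0) abort_field("dem$cellsize_m", "must be > 0")
  structure(
    list(
      n_settlements = as.integer(n_settlements), n_regions = as.integer(n_regions),
      rank_size_exponent = rank_size_exponent, top_population = top_population,
      bbox = unname(bbox), n_clusters = as.integer(n_clusters),
      cluster_sd_km = cluster_sd_km, cluster_fraction = cluster_fraction,
      dem = dem, road_detour = road_detour, true_params = true_params,
      mobility_rate = mobility_rate, growth_factor = growth_factor,
      interval = as.character(interval), seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic settlement table
#'
#' Coordinates are a mixture of a uniform background and Gaussian clusters
#' inside the bounding box; populations follow the deterministic rank-size
#' rule `P_r = round(top_population * r^-s)` in id order (the rank-1
#' settlement is `S0001`); regions are assigned by the nearest of
#' `n_regions` uniformly placed seed points. Fully reproducible for a fixed
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `id`, `name`, `x`, `y`, `region` and
#'   `pop_<start wave>`, with the coordinate convention (`"planar_km"`)
#'   recorded in the `coords` attribute.
#' @export
#' @examples
#' st <- generate_settlements(synthetic_config(n_settlements = 20, seed = 3))
#' head(st)
generate_settlements <- function(config) {
  n <- config$n_settlements
  bb <- config$bbox
  with_substream(config$seed, "settlements", {
    centers <- cbind(runif(max(config$n_clusters, 1), bb[1], bb[3]),
                     runif(max(config$n_clusters, 1), bb[2], bb[4]))
    clustered <- if (config$n_clusters > 0) {
      runif(n) < config$cluster_fraction
    } else {
      rep(FALSE, n)
    }
    pick <- sample.int(max(config$n_clusters, 1), n, replace = TRUE)
    x <- ifelse(clustered, centers[pick, 1] + rnorm(n, 0, config$cluster_sd_km),
                runif(n, bb[1], bb[3]))
    y <- ifelse(clustered, centers[pick, 2] + rnorm(n, 0, config$cluster_sd_km),
                runif(n, bb[2], bb[4]))
    x <- pmin(pmax(x, bb[1]), bb[3])
    y <- pmin(pmax(y, bb[2]), bb[4])
    region_seeds <- cbind(runif(config$n_regions, bb[1], bb[3]),
                          runif(config$n_regions, bb[2], bb[4]))
    nearest_region <- apply(
      outer(x, region_seeds[, 1], "-")^2 + outer(y, region_seeds[, 2], "-")^2,
      1, which.min
    )
    r <- seq_len(n)
    pop <- round(config$top_population * r^(-config$rank_size_exponent))
    out <- tibble::tibble(
      id = sprintf("S%04d", r),
      name = sprintf("Settlement %d", r),
      x = x, y = y,
      region = sprintf("R%d", nearest_region)
    )
    out[[paste0("pop_", config$interval[1])]] <- pop
    attr(out, "coords") <- "planar_km"
    out
  })
}

#' Generate a synthetic DEM with ridge structure
#'
#' Elevation is a sum of anisotropic Gaussian ridges (random centre,
#' orientation and length, Gaussian cross-section) plus smoothed Gaussian
#' noise, on a regular grid covering the config bounding box. A config with
#' zero ridges and zero noise yields a flat grid.
#'
#' @param config A [synthetic_config()].
#' @return A [dem_grid()] in metres, row 1 at the top (north).
#' @export
generate_dem <- function(config) {
  bb <- config$bbox
  cs_km <- config$dem$cellsize_m / 1000
  ncol <- config$dem$ncol %||% max(3L, as.integer(ceiling((bb[3] - bb[1]) / cs_km)))
  nrow <- config$dem$nrow %||% max(3L, as.integer(ceiling((bb[4] - bb[2]) / cs_km)))
  if (nrow < 3 || ncol < 3) abort_field("dem", "grid must be at least 3x3")
  # cell-centre coordinates; row 1 is the northernmost row
  cx <- bb[1] + (seq_len(ncol) - 0.5) * cs_km
  cy <- bb[2] + (nrow - seq_len(nrow) + 0.5) * cs_km
  X <- matrix(cx, nrow, ncol, byrow = TRUE)
  Y <- matrix(cy, nrow, ncol)
  with_substream(config$seed, "dem", {
    z <- matrix(0, nrow, ncol)
    if (config$dem$n_ridges > 0 && config$dem$ridge_amplitude_m > 0) {
      for (i in seq_len(config$dem$n_ridges)) {
        ctr <- c(runif(1, bb[1], bb[3]), runif(1, bb[2], bb[4]))
        theta <- runif(1, 0, pi)
        amp <- config$dem$ridge_amplitude_m * runif(1, 0.6, 1)
        half <- config$dem$ridge_length_km * runif(1, 0.6, 1) / 2
        u <- c(cos(theta), sin(theta))
        # distance from each cell centre to the ridge axis segment
        px <- X - ctr[1]
        py <- Y - ctr[2]
        along <- pmin(pmax(px * u[1] + py * u[2], -half), half)
        dx <- px - along * u[1]
        dy <- py - along * u[2]
        z <- z + amp * exp(-(dx^2 + dy^2) / (2 * config$dem$ridge_width_km^2))
      }
    }
    if (config$dem$noise_sd_m > 0) {
      noise <- matrix(rnorm(nrow * ncol, 0, config$dem$noise_sd_m), nrow, ncol)
      z <- z + smooth_matrix(noise, config$dem$noise_smooth_cells)
    }
    dem_grid(z, cellsize_m = config$dem$cellsize_m, xll = bb[1], yll = bb[2])
  })
}

# Separable box smoothing with edge renormalisation (window = 2*cells + 1).
smooth_matrix <- function(m, cells) {
  if (cells < 1) return(m)
  k <- 2L * as.integer(cells) + 1L
  smooth1 <- function(mat) {
    n <- nrow(mat)
    csum <- apply(rbind(0, mat), 2, cumsum)
    lo <- pmax(seq_len(n) - cells, 1L)
    hi <- pmin(seq_len(n) + cells, n)
    (csum[hi + 1L, , drop = FALSE] - csum[lo, , drop = FALSE]) / (hi - lo + 1L)
  }
  t(smooth1(t(smooth1(m))))
}

#' Generate a synthetic road graph over settlements
#'
#' Builds the Gabriel graph of the settlement points (an edge joins two
#' settlements when no third settlement lies inside the circle having the
#' pair as diameter), then multiplies each edge's Euclidean length by a
#' lognormal detour factor truncated below at 1. The Gabriel graph contains
#' the Euclidean minimum spanning tree, so the result is connected; a
#' defensive MST augmentation guards degenerate inputs.
#'
#' @param settlements Settlement table with planar-km coordinates.
#' @param config A [synthetic_config()] (supplies the detour distribution
#'   and seed).
#' @return A `road_graph`: list with `nodes` (id, x, y) and `edges`
#'   (from, to, length_km) tibbles.
#' @export
generate_road_graph <- function(settlements, config) {
  validate_settlements(settlements)
  n <- nrow(settlements)
  if (n < 2) abort_field("settlements", "need at least 2 settlements for a road graph")
  xy <- cbind(settlements$x, settlements$y)
  D2 <- as.matrix(stats::dist(xy))^2
  edges <- gabriel_edges(D2)
  with_substream(config$seed, "roads", {
    detour <- pmax(1, rlnorm(nrow(edges), config$road_detour$meanlog, config$road_detour$sdlog))
    len <- sqrt(D2[edges]) * detour
    g <- road_graph(
      nodes = tibble::tibble(id = settlements$id, x = settlements$x, y = settlements$y),
      edges = tibble::tibble(
        from = settlements$id[edges[, 1]],
        to = settlements$id[edges[, 2]],
        length_km = len
      )
    )
    ensure_connected(g, xy)
  })
}

# Gabriel condition for pair (i, j): no k with d(i,k)^2 + d(j,k)^2 < d(i,j)^2.
gabriel_edges <- function(D2) {
  n <- nrow(D2)
  out <- vector("list", n)
  for (i in seq_len(n - 1)) {
    W <- sweep(D2, 2, D2[i, ], "+")        # W[j, k] = d(j,k)^2 + d(i,k)^2
    mins <- apply(W, 1, min)               # k = i and k = j give equality, not <
    j <- which(seq_len(n) > i & mins >= D2[i, ] * (1 - 1e-12))
    out[[i]] <- cbind(rep.int(i, length(j)), j)
  }
  do.call(rbind, out)
}

# Defensive: add Euclidean MST edges for any missing connectivity.
ensure_connected <- function(g, xy) {
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE, vertices = g$nodes)
  if (igraph::components(ig)$no == 1L) return(g)
  full <- igraph::graph_from_adjacency_matrix(as.matrix(stats::dist(xy)),
    mode = "undirected", weighted = TRUE
  )
  igraph::V(full)$name <- g$nodes$id
  mst <- igraph::as_data_frame(igraph::mst(full), what = "edges")
  extra <- tibble::tibble(from = mst$from, to = mst$to, length_km = mst$weight)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  extra <- extra[!key(extra$from, extra$to) %in% key(g$edges$from, g$edges$to), ]
  g$edges <- dplyr::bind_rows(g$edges, extra)
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE, vertices = g$nodes)
  if (igraph::components(ig)$no != 1L) {
    abort("internal error: road graph disconnected after MST augmentation")
  }
  g
}

#' Simulate one intercensal interval of gravity migration
#'
#' Expected flows follow the gravity law under the config's ground-truth
#' parameters, with the scaling constant normalised so that expected flows
#' sum to the gross volume `T = mobility_rate * sum(start population)`.
#' Realised flows are independent Poisson draws around the expectation
#' (`noise = "poisson"`), or the expectation itself (`noise = "none"`, used
#' for noiseless parameter-recovery oracles). End populations are
#' `round(g * start) + inflow - outflow` (no rounding in the noiseless
#' case), clamped at zero with a diagnostic count.
#'
#' @param settlements Settlement table with the start-wave population.
#' @param distances A [dist_matrix()] over the same settlements.
#' @param config A [synthetic_config()].
#' @param noise `"poisson"` (default) or `"none"`.
#' @return A `synthetic_world`: list with the settlement table extended by
#'   the end-wave population, the realised `flows` and `expected_flows`
#'   matrices, the normalised `true_params`, the gross volume `total`, the
#'   clamped-settlement count and the seed.
#' @export
simulate_interval <- function(settlements, distances, config, noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  validate_settlements(settlements)
  start <- pop_vector(settlements, config$interval[1])
  if (any(start <= 0)) abort_field("settlements", "start populations must be > 0")
  D <- as.matrix(distances)
  if (any(D[upper.tri(D)] <= 0)) abort_field("distances", "off-diagonal distances must be > 0")
  params <- config$true_params
  total <- config$mobility_rate * sum(start)
  params$k <- normalise_k(settlements, distances, params, total, wave = config$interval[1])
  expected <- predict_flows(settlements, distances, params, wave = config$interval[1])
  realised <- expected
  if (noise == "poisson") {
    realised[] <- with_substream(config$seed, "flows", {
      m <- matrix(rpois(length(expected), lambda = as.vector(expected)),
                  nrow(expected), ncol(expected))
      diag(m) <- 0
      m
    })
  }
  s <- flow_summary(realised)
  g <- config$growth_factor
  base_end <- if (noise == "poisson") round(g * start) else g * start
  end <- base_end + s$net[align_ids(s$id, names(start), "flow summary")]
  clamped <- sum(end < 0)
  end <- pmax(end, 0)
  if (clamped > 0.01 * length(end)) {
    warn(sprintf(
      "mobility_rate too aggressive: %d settlements clamped at zero population",
      clamped
    ))
  }
  out <- settlements
  out[[paste0("pop_", config$interval[2])]] <- unname(end)
  structure(
    list(
      settlements = out, flows = realised, expected_flows = expected,
      true_params = params, total = total, growth_factor = g,
      interval = config$interval, clamped = clamped, seed = config$seed
    ),
    class = "synthetic_world"
  )
}

#' Generate a complete synthetic world
#'
#' Convenience orchestrator: settlements, DEM, road graph, Euclidean
#' distances and one simulated migration interval, each drawn from its own
#' named substream of the config seed.
#'
#' @inheritParams simulate_interval
#' @param config A [synthetic_config()].
#' @return A `synthetic_world` with `dem` and `roads` attached.
#' @export
#' @examples
#' w <- generate_world(synthetic_config(n_settlements = 30, seed = 11))
#' sum(w$flows)
generate_world <- function(config, noise = c("poisson", "none")) {
  st <- generate_settlements(config)
  dem <- generate_dem(config)
  roads <- generate_road_graph(st, config)
  d <- euclidean_matrix(st)
  world <- simulate_interval(st, d, config, noise = match.arg(noise))
  world$dem <- dem
  world$roads <- roads
  world$distances <- d
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d settlements, interval %s-%s, gross volume %.0f, %d clamped\n",
    nrow(x$settlements), x$interval[1], x$interval[2], x$total, x$clamped
  ))
  invisible(x)
}
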