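test_that("planar Euclidean distances follow plane geometry", {
  st <- make_settlements(c("A", "B"), x = c(0, 3), y = c(0, 4))
  d <- euclidean_matrix(st)
  expect_equal(d["A", "B"], 5)
  expect_equal(d["B", "A"], 5)
  expect_equal(diag(d), c(A = 0, B = 0))
})

test_that("lon/lat distances use the great circle on a 6371 km sphere", {
  st <- make_settlements(c("A", "B"), x = c(0, 1), y = c(0, 0))
  attr(st, "coords") <- "lonlat"
  d <- euclidean_matrix(st)
  expect_equal(d["A", "B"], pi * 6371 / 180, tolerance = 1e-7)
})

test_that("duplicate coordinates are a validation error naming the pair", {
  st <- make_settlements(c("A", "B", "C"), x = c(0, 0, 5), y = c(1, 1, 1))
  expect_error(euclidean_matrix(st), "A-B")
})

test_that("network distances on toy graphs match path arithmetic", {
  # settlements at the two nodes of a single 5 km edge
  st <- make_settlements(c("A", "B"), x = c(0, 5), y = c(0, 0))
  g <- road_graph(
    nodes = tibble::tibble(id = c("A", "B"), x = c(0, 5), y = c(0, 0)),
    edges = tibble::tibble(from = "A", to = "B", length_km = 5)
  )
  expect_equal(network_matrix(st, g)["A", "B"], 5)

  # path A-B-C with edges 5 and 7 km
  st3 <- make_settlements(c("A", "C"), x = c(0, 12), y = c(0, 0))
  g3 <- road_graph(
    nodes = tibble::tibble(id = c("A", "B", "C"), x = c(0, 5, 12), y = 0),
    edges = tibble::tibble(from = c("A", "B"), to = c("B", "C"), length_km = c(5, 7))
  )
  expect_equal(network_matrix(st3, g3)["A", "C"], 12)

  # snapping: settlement 1 km from node A of a 5 km edge, second at B
  sts <- make_settlements(c("P", "Q"), x = c(-1, 5), y = c(0, 0))
  gs <- road_graph(
    nodes = tibble::tibble(id = c("A", "B"), x = c(0, 5), y = c(0, 0)),
    edges = tibble::tibble(from = "A", to = "B", length_km = 5)
  )
  expect_equal(network_matrix(sts, gs)["P", "Q"], 6)
})

test_that("network distances equal exhaustive shortest paths on small graphs", {
  set.seed(71)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    xy <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    # random connected graph: a random tree plus extra edges
    tree <- tibble::tibble(i = 2:n, j = vapply(2:n, function(v) sample(v - 1, 1), 1L))
    extra_n <- sample(0:4, 1)
    extra <- tibble::tibble(
      i = sample(n, extra_n, replace = TRUE),
      j = sample(n, extra_n, replace = TRUE)
    )
    edges <- rbind(tree, extra)
    edges <- edges[edges$i != edges$j, ]
    euclid <- sqrt(rowSums((xy[edges$i, , drop = FALSE] - xy[edges$j, , drop = FALSE])^2))
    edges$w <- euclid * runif(nrow(edges), 1, 1.5)

    ids <- sprintf("N%02d", seq_len(n))
    st <- make_settlements(ids, x = xy[, 1], y = xy[, 2])
    g <- road_graph(
      nodes = tibble::tibble(id = ids, x = xy[, 1], y = xy[, 2]),
      edges = tibble::tibble(from = ids[edges$i], to = ids[edges$j], length_km = edges$w)
    )
    got <- network_matrix(st, g)
    want <- floyd_warshall(n, edges)
    dimnames(want) <- list(ids, ids)
    expect_equal(unclass(got), want, ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("unreachable pairs and empty graphs are errors, not infinities", {
  st <- make_settlements(c("A", "B"), x = c(0, 10), y = c(0, 0))
  g <- road_graph(
    nodes = tibble::tibble(id = c("A", "B", "C", "D"), x = c(0, 10, 0.1, 9.9), y = c(0, 0, 0, 0)),
    edges = tibble::tibble(from = c("A", "B"), to = c("C", "D"), length_km = c(0.1, 0.1))
  )
  expect_error(network_matrix(st, g), "disconnected")
  g0 <- list(nodes = tibble::tibble(id = "A", x = 0, y = 0),
             edges = tibble::tibble(from = character(), to = character(),
                                    length_km = numeric()))
  expect_error(network_matrix(st, g0), "no edges")
})

test_that("elongation ratios compare network to straight-line separation", {
  st <- make_settlements(c("A", "B"), x = c(0, 5), y = c(0, 0))
  e <- euclidean_matrix(st)
  expect_equal(elongation_summary(e, e)$summary$mean, 1)

  n6 <- e
  n6["A", "B"] <- n6["B", "A"] <- 6
  n6 <- dist_matrix(unclass(n6), kind = "network")
  el <- elongation_summary(e, n6)
  expect_equal(el$pairs$ratio, 1.2)

  short <- e
  short["A", "B"] <- short["B", "A"] <- 4
  short <- dist_matrix(unclass(short), kind = "network")
  expect_warning(elongation_summary(e, short), "below Euclidean")
})

test_that("synthetic road networks never undercut straight-line distance", {
  cfg <- synthetic_config(n_settlements = 40, seed = 14)
  st <- generate_settlements(cfg)
  g <- generate_road_graph(st, cfg)
  e <- euclidean_matrix(st)
  nm <- network_matrix(st, g)
  el <- elongation_summary(e, nm)
  # triangle inequality: edges >= chords and Euclidean connectors imply
  # network >= Euclidean for every pair
  expect_gte(el$summary$min, 1)
  expect_equal(unclass(nm), unclass(t(nm)), ignore_attr = TRUE)
  expect_true(all(diag(nm) == 0))
})

test_that("distance matrices reject asymmetry, infinities and zero pairs", {
  m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_s3_class(dist_matrix(m), "dist_matrix")
  bad <- m; bad[1, 2] <- 2
  expect_error(dist_matrix(bad), "symmetric")
  inf <- m; inf[1, 2] <- inf[2, 1] <- Inf
  expect_error(dist_matrix(inf), "finite")
  zero <- m; zero[1, 2] <- zero[2, 1] <- 0
  expect_error(dist_matrix(zero), "zero or negative")
})
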