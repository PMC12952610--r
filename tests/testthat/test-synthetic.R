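test_that("rank-size populations follow the deterministic Zipf rule", {
  cfg <- synthetic_config(n_settlements = 100, top_population = 10000,
                          rank_size_exponent = 1, seed = 5)
  st <- generate_settlements(cfg)
  expect_equal(st[[paste0("pop_", cfg$interval[1])]][2], 5000)

  cfg2 <- synthetic_config(n_settlements = 100, top_population = 10000,
                           rank_size_exponent = 1.1, seed = 5)
  st2 <- generate_settlements(cfg2)
  pops <- st2$pop_t0
  expect_equal(pops, round(10000 * (1:100)^(-1.1)))
  expect_true(all(diff(pops) <= 0))
})

test_that("settlement generation is deterministic and bounded by the bbox", {
  cfg <- synthetic_config(n_settlements = 80, seed = 42)
  a <- generate_settlements(cfg)
  b <- generate_settlements(cfg)
  expect_identical(a, b)
  expect_true(all(a$x >= cfg$bbox[1] & a$x <= cfg$bbox[3]))
  expect_true(all(a$y >= cfg$bbox[2] & a$y <= cfg$bbox[4]))
  expect_false(anyDuplicated(a$id) > 0)
  expect_true(all(a$region %in% sprintf("R%d", 1:7)))
})

test_that("degenerate rank-size configs are rejected naming the field", {
  expect_error(
    synthetic_config(n_settlements = 1000, top_population = 50, rank_size_exponent = 2),
    "top_population"
  )
  expect_error(synthetic_config(n_settlements = 0), "n_settlements")
  expect_error(synthetic_config(mobility_rate = 1), "mobility_rate")
})

test_that("DEM generation honours degenerate and enveloped configs", {
  flat <- synthetic_config(
    n_settlements = 5, seed = 1,
    dem = list(n_ridges = 0, noise_sd_m = 0, nrow = 10, ncol = 12)
  )
  d <- generate_dem(flat)
  expect_true(all(d$elev == d$elev[1, 1]))
  expect_equal(dim(d$elev), c(10L, 12L))

  one <- synthetic_config(
    n_settlements = 5, seed = 2,
    dem = list(n_ridges = 1, ridge_amplitude_m = 500, noise_sd_m = 0,
               nrow = 30, ncol = 30)
  )
  d1 <- generate_dem(one)
  expect_true(all(is.finite(d1$elev)))
  expect_lte(max(d1$elev), 500)
  expect_gte(min(d1$elev), 0)

  expect_identical(generate_dem(one)$elev, d1$elev)
})

test_that("road graphs are connected with chord-length edges when detour is 1", {
  cfg <- synthetic_config(
    n_settlements = 50, seed = 9,
    road_detour = list(meanlog = 0, sdlog = 0)
  )
  st <- generate_settlements(cfg)
  g <- generate_road_graph(st, cfg)

  # detour == 1: every edge weight equals the endpoint Euclidean distance
  ii <- match(g$edges$from, st$id)
  jj <- match(g$edges$to, st$id)
  chord <- sqrt((st$x[ii] - st$x[jj])^2 + (st$y[ii] - st$y[jj])^2)
  expect_equal(g$edges$length_km, chord, tolerance = 1e-12)

  # single component, checked with an independent BFS oracle
  seen <- bfs_reachable(nrow(st), match(g$edges$from, st$id), match(g$edges$to, st$id))
  expect_true(all(seen))
})

test_that("two settlements a known distance apart yield one edge of that length", {
  st <- make_settlements(c("A", "B"), x = c(0, 10), y = c(0, 0), pop_t0 = c(100, 50))
  cfg <- synthetic_config(n_settlements = 2, seed = 1,
                          road_detour = list(meanlog = 0, sdlog = 0))
  g <- generate_road_graph(st, cfg)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$length_km, 10)
})

test_that("zero mobility produces zero flows and pure natural growth", {
  cfg <- synthetic_config(n_settlements = 25, mobility_rate = 0,
                          growth_factor = 1.2, seed = 3)
  st <- generate_settlements(cfg)
  d <- euclidean_matrix(st)
  w <- simulate_interval(st, d, cfg)
  expect_true(all(w$flows == 0))
  expect_equal(
    w$settlements$pop_t1,
    round(1.2 * w$settlements$pop_t0)
  )
})

test_that("simulated intervals are reproducible and conserve net migration", {
  cfg <- synthetic_config(n_settlements = 40, seed = 21)
  st <- generate_settlements(cfg)
  d <- euclidean_matrix(st)
  w1 <- simulate_interval(st, d, cfg)
  w2 <- simulate_interval(st, d, cfg)
  expect_identical(w1$flows, w2$flows)
  s <- flow_summary(w1$flows)
  expect_equal(sum(s$net), 0)
  expect_true(all(diag(w1$flows) == 0))
})

test_that("realised Poisson totals concentrate around the gross volume", {
  cfg <- synthetic_config(n_settlements = 200, mobility_rate = 0.05, seed = 1)
  st <- generate_settlements(cfg)
  d <- euclidean_matrix(st)
  totals <- vapply(1:100, function(s) {
    cfg$seed <- s
    sum(simulate_interval(st, d, cfg)$flows)
  }, numeric(1))
  T0 <- cfg$mobility_rate * sum(st$pop_t0)
  # Poisson-sum oracle: the grand total is Poisson(T), so Var = T and the
  # mean of R replicates has standard error sqrt(T / R)
  se <- sqrt(T0 / length(totals))
  expect_lt(abs(mean(totals) - T0), 3 * se)
})

test_that("noiseless simulation returns the expected flows exactly", {
  cfg <- synthetic_config(n_settlements = 30, seed = 8)
  st <- generate_settlements(cfg)
  d <- euclidean_matrix(st)
  w <- simulate_interval(st, d, cfg, noise = "none")
  expect_identical(unclass(w$flows), unclass(w$expected_flows))
  expect_equal(sum(w$flows), w$total, tolerance = 1e-9)
  # end totals follow g * start exactly when nothing is clamped
  expect_equal(
    sum(w$settlements$pop_t1),
    cfg$growth_factor * sum(w$settlements$pop_t0),
    tolerance = 1e-9
  )
})
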