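test_that("decay kernels match their closed forms", {
  expect_equal(decay(1, 2.7, "power"), 1)
  expect_equal(decay(2, 1, "power"), 0.5)
  expect_equal(decay(c(1, 5, 90), 0, "exponential"), c(1, 1, 1))
  expect_equal(decay(log(2), 1, "exponential"), 0.5)
  expect_error(decay(0, 1, "power"), "d > 0")
  expect_error(decay(-1, 1, "exponential"), ">= 0")
})

test_that("k normalisation reproduces the two-settlement hand computation", {
  st <- make_settlements(c("A", "B"), x = c(0, 1), y = c(0, 0), pop_t0 = c(10, 10))
  d <- euclidean_matrix(st)
  p <- model_params("power", beta = 1, gamma = 1)
  # denominator: 10*10^1*1 + 10*10^1*1 = 200
  expect_equal(normalise_k(st, d, p, total = 100), 0.5)
  expect_equal(normalise_k(st, d, p, total = 0), 0)
  expect_equal(normalise_k(st, d, p, total = 200), 1.0) # linear in T
})

test_that("predicted flows conserve the total and respect symmetry", {
  st <- make_settlements(c("A", "B"), x = c(0, 7), y = c(0, 0), pop_t0 = c(500, 500))
  d <- euclidean_matrix(st)
  p <- model_params("exponential", beta = 0.3, gamma = 1.4)
  p$k <- normalise_k(st, d, p, total = 120)
  f <- predict_flows(st, d, p)
  expect_equal(f["A", "B"], f["B", "A"]) # equal populations
  expect_equal(sum(f), 120, tolerance = 1e-9)
})

test_that("flow prediction equals the naive double loop on small systems", {
  set.seed(90)
  for (fam in c("power", "exponential")) {
    n <- 8
    ids <- sprintf("S%d", 1:n)
    st <- make_settlements(ids, x = runif(n, 0, 100), y = runif(n, 0, 100),
                           pop_t0 = sample(100:5000, n))
    d <- euclidean_matrix(st)
    p <- model_params(fam, beta = 1.2, gamma = 1.5)
    p$k <- normalise_k(st, d, p, total = 1000)
    got <- predict_flows(st, d, p)
    want <- naive_predict(pop_vector(st), as.matrix(d), p$k, p$gamma, p$beta, fam)
    expect_equal(unclass(got), want, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("the three-settlement toy matches scalar arithmetic term by term", {
  ids <- c("A", "B", "C")
  # place so pairwise distances are exactly 10, 20, 30 km (collinear)
  st <- make_settlements(ids, x = c(0, 10, 30), y = 0, pop_t0 = c(100, 200, 400))
  d <- euclidean_matrix(st)
  expect_equal(d["A", "B"], 10)
  expect_equal(d["B", "C"], 20)
  expect_equal(d["A", "C"], 30)
  p <- model_params("power", beta = 1, gamma = 1.5)
  pop <- c(A = 100, B = 200, C = 400)
  terms <- c(
    AB = 100 * 200^1.5 / 10, AC = 100 * 400^1.5 / 30,
    BA = 200 * 100^1.5 / 10, BC = 200 * 400^1.5 / 20,
    CA = 400 * 100^1.5 / 30, CB = 400 * 200^1.5 / 20
  )
  k <- 50 / sum(terms)
  p$k <- normalise_k(st, d, p, total = 50)
  expect_equal(p$k, k, tolerance = 1e-12)
  f <- predict_flows(st, d, p)
  expect_equal(f["A", "B"], k * terms[["AB"]], tolerance = 1e-12)
  expect_equal(f["C", "A"], k * terms[["CA"]], tolerance = 1e-12)
  expect_equal(sum(f), 50, tolerance = 1e-9)
})

test_that("flow summaries match independent row/column summation", {
  m <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  m["A", "B"] <- 5
  s <- flow_summary(flow_matrix(m))
  expect_equal(s$outflow[s$id == "A"], 5)
  expect_equal(s$inflow[s$id == "B"], 5)
  expect_equal(s$net, c(-5, 5))

  sym <- matrix(2, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(sym) <- 0
  expect_equal(flow_summary(flow_matrix(sym))$net, c(0, 0, 0))

  set.seed(6)
  r <- matrix(rpois(36, 4), 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  diag(r) <- 0
  s6 <- flow_summary(flow_matrix(r))
  for (i in 1:6) {
    expect_equal(s6$inflow[i], sum(r[, i]))
    expect_equal(s6$outflow[i], sum(r[i, ]))
  }
  expect_equal(sum(s6$net), 0)
})

test_that("interval targets absorb uniform growth and balance exactly", {
  st <- make_settlements(c("A", "B"), x = c(0, 1), y = 0,
                         pop_a = c(100, 100), pop_b = c(130, 90))
  t1 <- derive_targets(st, "a", "b")
  expect_equal(t1$growth_factor, 1.1)
  expect_equal(t1$table$baseline, c(110, 110))
  expect_equal(t1$table$delta, c(20, -20))
  expect_equal(t1$total, 20)
  expect_equal(sum(t1$table$delta), 0, tolerance = 1e-9)

  same <- make_settlements("A", 0, 0, pop_a = 50, pop_b = 50)
  expect_equal(derive_targets(same, "a", "b")$total, 0)

  dbl <- make_settlements(c("A", "B"), x = c(0, 1), y = 0,
                          pop_a = c(10, 30), pop_b = c(20, 60))
  t2 <- derive_targets(dbl, "a", "b")
  expect_equal(t2$table$delta, c(0, 0))
  expect_equal(t2$total, 0)
})

test_that("population projection applies growth plus net migration", {
  st <- make_settlements(c("A", "B"), x = c(0, 1), y = 0, pop_t0 = c(100, 200))
  s0 <- tibble::tibble(id = c("A", "B"), inflow = 0, outflow = 0, net = c(0, 0))
  expect_equal(project_population(st, 1, s0)$projected, c(100, 200))

  s1 <- tibble::tibble(id = c("A", "B"), inflow = 0, outflow = 5, net = c(-5, 5))
  expect_equal(project_population(st, 1.1, s1)$projected[1], 105)

  cfg <- synthetic_config(n_settlements = 30, seed = 17)
  w <- generate_world(cfg, noise = "none")
  s <- flow_summary(w$flows)
  proj <- project_population(w$settlements, w$growth_factor, s, wave = "t0")
  expect_equal(attr(proj, "clamped"), 0)
  expect_equal(sum(proj$projected),
               w$growth_factor * sum(w$settlements$pop_t0),
               tolerance = 1e-9)
})

test_that("stronger decay shifts flow towards the shortest pair", {
  set.seed(55)
  n <- 10
  st <- make_settlements(sprintf("S%d", 1:n), x = runif(n, 0, 200), y = runif(n, 0, 150),
                         pop_t0 = sample(500:20000, n))
  d <- euclidean_matrix(st)
  off <- which(upper.tri(d), arr.ind = TRUE)
  shortest <- off[which.min(d[off]), ]
  for (fam in c("power", "exponential")) {
    prev_raw <- NULL
    prev_share <- -Inf
    for (b in c(0.5, 1, 1.5, 2, 2.5)) {
      p <- model_params(fam, beta = b, gamma = 1.5, k = 1)
      raw <- predict_flows(st, d, p) # unnormalised (k = 1)
      if (!is.null(prev_raw)) {
        # before re-normalisation every flow with d > 1 km strictly decreases
        far <- as.matrix(d) > 1 & row(d) != col(d)
        if (fam == "exponential") far <- as.matrix(d) > 0 & row(d) != col(d)
        expect_true(all(raw[far] < prev_raw[far]))
      }
      prev_raw <- raw
      share <- raw[shortest[1], shortest[2]] / sum(raw)
      expect_gte(share, prev_share)
      prev_share <- share
    }
  }
})
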