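# Independent brute-force oracles and tiny fixture builders shared across
# the suite. Oracles are deliberately naive (double loops, exhaustive
# relaxation) and never call the code paths they check.

make_settlements <- function(ids, x, y, region = "R1", ...) {
  pops <- list(...)
  out <- tibble::tibble(id = ids, name = ids, x = x, y = y, region = region)
  for (nm in names(pops)) out[[nm]] <- pops[[nm]]
  attr(out, "coords") <- "planar_km"
  out
}

# Naive gravity prediction: explicit scalar double loop.
naive_predict <- function(pop, D, k, gamma, beta, family) {
  n <- length(pop)
  out <- matrix(0, n, n, dimnames = list(names(pop), names(pop)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      f <- if (family == "power") D[i, j]^(-beta) else exp(-beta * D[i, j])
      out[i, j] <- k * pop[i] * pop[j]^gamma * f
    }
  }
  out
}

# All-pairs shortest paths by exhaustive Floyd-Warshall relaxation.
floyd_warshall <- function(n, edges) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (e in seq_len(nrow(edges))) {
    i <- edges$i[e]; j <- edges$j[e]; w <- edges$w[e]
    d[i, j] <- min(d[i, j], w)
    d[j, i] <- min(d[j, i], w)
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Naive TRI: scalar loop over interior cells and their 8 neighbours.
naive_tri <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (r in 2:(nr - 1)) {
    for (c in 2:(nc - 1)) {
      acc <- 0
      ok <- TRUE
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          v <- z[r + dr, c + dc]
          if (is.na(v) || is.na(z[r, c])) ok <- FALSE else acc <- acc + (v - z[r, c])^2
        }
      }
      if (ok) out[r, c] <- sqrt(acc)
    }
  }
  out
}

# Naive regional aggregation: scalar loop group-by.
naive_aggregate <- function(m, region) {
  labs <- sort(unique(unname(region)))
  out <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in rownames(m)) {
    for (j in colnames(m)) {
      out[region[[i]], region[[j]]] <- out[region[[i]], region[[j]]] + m[i, j]
    }
  }
  out
}

# Breadth-first search reachability from node 1 over an undirected edge list.
bfs_reachable <- function(n, from, to) {
  adj <- vector("list", n)
  for (e in seq_along(from)) {
    adj[[from[e]]] <- c(adj[[from[e]]], to[e])
    adj[[to[e]]] <- c(adj[[to[e]]], from[e])
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  seen
}

# Benchmark regional matrices (printed cells + printed marginal totals).
read_benchmark <- function(name) {
  path <- system.file("extdata", name, package = "gravityflow")
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}
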