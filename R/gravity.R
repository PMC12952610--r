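#' Gravity model parameters
#'
#' The unconstrained gravity model predicts the flow from origin `i` to
#' destination `j` as `F_ij = k * P_i * P_j^gamma * f(d_ij)`, where the
#' distance-decay kernel `f` is either the inverse power `d^-beta`
#' (dimensionless `beta`) or the exponential `exp(-beta * d)` (`beta` per
#' km). `gamma` scales the pull of destination population; `k` is the
#' scaling constant fixed by normalisation, never user-supplied.
#'
#' @param family `"power"` or `"exponential"`.
#' @param beta Distance-decay strength (>= 0). Not comparable across
#'   families.
#' @param gamma Destination population exponent (> 0).
#' @param k Scaling constant; leave `NA` until set by [normalise_k()].
#' @return A list of class `model_params`.
#' @export
#' @examples
#' model_params("power", beta = 1, gamma = 1.5)
model_params <- function(family = c("power", "exponential"), beta, gamma, k = NA_real_) {
  family <- match.arg(family)
  if (beta < 0) abort_field("beta", "must be >= 0")
  if (gamma <= 0) abort_field("gamma", "must be > 0")
  structure(list(family = family, beta = beta, gamma = gamma, k = k),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> %s decay, beta = %g, gamma = %g, k = %s\n",
    x$family, x$beta, x$gamma,
    if (is.na(x$k)) "unset" else format(x$k, digits = 6)
  ))
  invisible(x)
}

#' Distance-decay factor
#'
#' Power decay `d^-beta` (undefined at d = 0: self-pairs are excluded
#' structurally, so a zero distance here is a data fault) or exponential
#' decay `exp(-beta * d)`.
#'
#' @param d Distances in km (vectorised).
#' @param beta Decay parameter (>= 0).
#' @param family `"power"` or `"exponential"`.
#' @return Positive decay factors, same shape as `d`.
#' @export
#' @examples
#' decay(2, 1, "power")            # 0.5
#' decay(log(2), 1, "exponential") # 0.5
decay <- function(d, beta, family = c("power", "exponential")) {
  family <- match.arg(family)
  if (beta < 0) abort_field("beta", "must be >= 0")
  if (family == "power") {
    if (any(d <= 0)) abort_field("d", "power decay requires d > 0 (self-pairs are excluded upstream)")
    d^(-beta)
  } else {
    if (any(d < 0)) abort_field("d", "must be >= 0")
    exp(-beta * d)
  }
}

# Unnormalised gravity weight matrix P_i * P_j^gamma * f(d_ij), zero diagonal.
gravity_base <- function(pop, distances, params) {
  D <- as.matrix(distances)
  i <- align_ids(rownames(D), names(pop), "distance matrix")
  D <- D[i, i, drop = FALSE]
  off <- row(D) != col(D)
  W <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  W[off] <- decay(D[off], params$beta, params$family)
  B <- outer(pop, pop^params$gamma) * W
  diag(B) <- 0
  B
}

#' Normalise the gravity scaling constant
#'
#' Sets `k = T / sum over i != j of P_i * P_j^gamma * f(d_ij)` so that the
#' predicted flows sum exactly to the total volume `T` (the
#' total-constrained reading of the unconstrained model).
#'
#' @param settlements Settlement table.
#' @param distances A [dist_matrix()] covering the same settlements.
#' @param params A [model_params()].
#' @param total Total flow volume `T` (>= 0).
#' @param wave Census wave supplying the populations (default: first
#'   `pop_` column).
#' @return The scalar `k`.
#' @export
normalise_k <- function(settlements, distances, params, total, wave = NULL) {
  if (total < 0) abort_field("total", "must be >= 0")
  pop <- pop_vector(settlements, wave)
  if (any(pop <= 0)) abort_field("settlements", "populations must be > 0")
  if (length(pop) < 2 && total > 0) abort_field("settlements", "no settlement pairs to carry flow")
  if (total == 0) return(0)
  denom <- sum(gravity_base(pop, distances, params))
  if (!is.finite(denom) || denom <= 0) {
    abort_field("params", "gravity denominator underflowed or is non-finite")
  }
  total / denom
}

#' Flow matrix constructor
#'
#' Nonnegative origin x destination migrant counts (or real-valued
#' predictions) for one intercensal interval; the diagonal is structurally
#' excluded and held at zero.
#'
#' @param values Square nonnegative matrix, dimnames = settlement ids.
#' @param interval Optional two census wave labels `c(start, end)`.
#' @return The matrix with class `flow_matrix`.
#' @export
flow_matrix <- function(values, interval = NULL) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    abort_field("values", "must be a square matrix")
  }
  if (is.null(rownames(values))) abort_field("values", "must carry settlement ids as dimnames")
  if (any(!is.finite(values)) || any(values < 0)) {
    abort_field("values", "flows must be finite and nonnegative")
  }
  if (any(diag(values) != 0)) abort_field("values", "diagonal (self-flows) must be zero")
  structure(values, class = c("flow_matrix", "matrix"), interval = interval)
}

#' @export
print.flow_matrix <- function(x, ...) {
  iv <- attr(x, "interval")
  cat(sprintf(
    "<flow_matrix> %d settlements%s, total flow %.2f\n",
    nrow(x), if (is.null(iv)) "" else sprintf(", interval %s-%s", iv[1], iv[2]),
    sum(x)
  ))
  invisible(x)
}

#' Predict gravity flows
#'
#' Evaluates `F_ij = k * P_i * P_j^gamma * f(d_ij)` for every ordered pair
#' of distinct settlements. With `k` from [normalise_k()] the flows sum to
#' the normalisation total exactly (up to float round-off).
#'
#' @inheritParams normalise_k
#' @param params A [model_params()] with `k` set.
#' @param interval Optional interval labels attached to the result.
#' @return A [flow_matrix()].
#' @export
predict_flows <- function(settlements, distances, params, wave = NULL, interval = NULL) {
  if (is.na(params$k)) abort_field("params", "k is unset; call normalise_k() first")
  pop <- pop_vector(settlements, wave)
  flow_matrix(params$k * gravity_base(pop, distances, params), interval = interval)
}

#' Per-settlement migration summary
#'
#' Outflow is the row sum, inflow the column sum, net their difference;
#' net migration sums to zero over all settlements by construction.
#'
#' @param flows A [flow_matrix()] (any square flow matrix with id dimnames).
#' @return Tibble with `id`, `inflow`, `outflow`, `net`.
#' @export
flow_summary <- function(flows) {
  m <- as.matrix(flows)
  tibble::tibble(
    id = rownames(m),
    inflow = unname(colSums(m)),
    outflow = unname(rowSums(m)),
    net = unname(colSums(m) - rowSums(m))
  )
}

#' Derive intercensal targets from census stocks
#'
#' Census stocks identify migration only after natural change is removed.
#' The national growth factor `g = sum(end) / sum(start)` absorbs uniform
#' natural increase; the growth-adjusted baseline is `g * start`, the
#' net-migration target is `delta_i = end_i - g * start_i` (summing to zero
#' by construction), and the total migration volume is
#' `T = sum(max(0, delta_i))` -- the volume of net arrivals.
#'
#' @param settlements Settlement table with both wave columns.
#' @param start_wave,end_wave Census wave labels.
#' @return A list of class `interval_targets`: `table` (tibble with `id`,
#'   `start`, `end`, `baseline`, `delta`), `growth_factor`, `total`,
#'   `interval`.
#' @export
#' @examples
#' st <- tibble::tibble(id = c("A", "B"), x = 0, y = 0:1,
#'                      pop_a = c(100, 100), pop_b = c(130, 90))
#' derive_targets(st, "a", "b")$total # 20
derive_targets <- function(settlements, start_wave, end_wave) {
  start <- pop_vector(settlements, start_wave)
  end <- pop_vector(settlements, end_wave)
  if (sum(start) <= 0) abort_field("start_wave", "total start population must be > 0")
  g <- sum(end) / sum(start)
  delta <- end - g * start
  structure(
    list(
      table = tibble::tibble(
        id = names(start), start = unname(start), end = unname(end),
        baseline = unname(g * start), delta = unname(delta)
      ),
      growth_factor = g,
      total = sum(pmax(0, delta)),
      interval = c(start_wave, end_wave)
    ),
    class = "interval_targets"
  )
}

#' @export
print.interval_targets <- function(x, ...) {
  cat(sprintf(
    "<interval_targets> %s-%s: g = %.4f, T = %.1f over %d settlements\n",
    x$interval[1], x$interval[2], x$growth_factor, x$total, nrow(x$table)
  ))
  invisible(x)
}

#' @method tidy interval_targets
#' @export
tidy.interval_targets <- function(x, ...) x$table

#' Project end-of-interval populations
#'
#' `P_hat_i(end) = g * P_i(start) + net_i`, clamped at zero with a
#' diagnostic count (reported, never fatal). Without clamping the projected
#' total equals `g * sum(start)` exactly.
#'
#' @param settlements Settlement table with the start wave.
#' @param g National growth factor.
#' @param summary A migration summary from [flow_summary()].
#' @param wave Start census wave label.
#' @return Tibble with `id`, `projected`; the number of clamped settlements
#'   is attached as attribute `clamped`.
#' @export
project_population <- function(settlements, g, summary, wave = NULL) {
  start <- pop_vector(settlements, wave)
  net <- setNames(summary$net, summary$id)[names(start)]
  if (anyNA(net)) abort_field("summary", "missing net migration for some settlements")
  proj <- g * start + net
  clamped <- sum(proj < 0)
  if (clamped > 0) {
    inform(sprintf("%d projected population(s) clamped at zero", clamped))
  }
  out <- tibble::tibble(id = names(start), projected = unname(pmax(proj, 0)))
  attr(out, "clamped") <- clamped
  out
}

#' Flow matrix in long format
#'
#' @param flows A [flow_matrix()].
#' @param drop_zero Drop zero-flow pairs (default TRUE).
#' @return Tibble with `origin`, `destination`, `flow`.
#' @export
flows_to_long <- function(flows, drop_zero = TRUE) {
  m <- as.matrix(flows)
  ids <- rownames(m)
  idx <- which(row(m) != col(m) & (!drop_zero | m > 0), arr.ind = TRUE)
  tibble::tibble(
    origin = ids[idx[, 1]],
    destination = ids[idx[, 2]],
    flow = m[idx]
  ) |> dplyr::arrange(.data$origin, .data$destination)
}

#' Build a flow matrix from long-format records
#'
#' @param long Tibble with `origin`, `destination`, `flow`.
#' @param ids Full settlement id set (defaults to ids present in `long`).
#' @param interval Optional interval labels.
#' @return A [flow_matrix()]; absent pairs are zero.
#' @export
long_to_flows <- function(long, ids = NULL, interval = NULL) {
  ids <- ids %||% sort(unique(c(long$origin, long$destination)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(match(long$origin, ids), match(long$destination, ids))] <- long$flow
  flow_matrix(m, interval = interval)
}
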