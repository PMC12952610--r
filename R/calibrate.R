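#' Calibration grid specification
#'
#' Default grids follow the standard calibration ranges for national
#' migration systems: population-scaling exponent gamma from 1.2 to 1.9 in
#' steps of 0.1 and distance-decay beta from 0.5 to 3.0 (step 0.25, fine
#' enough to separate optima at 0.5 and 1.0 while keeping the grid small),
#' for both decay families.
#'
#' @param gamma Numeric vector of population-scaling values.
#' @param beta Numeric vector of distance-decay values.
#' @param families Decay families to calibrate (both by default; beta is
#'   family-specific and never compared across families).
#' @param objective Selection metric, minimised over the grid: `"srmse"`
#'   (default), `"mae"` or `"mape"`, computed on projected vs observed end
#'   populations.
#' @return A list of class `grid_spec`.
#' @export
#' @examples
#' length(grid_spec()$gamma) * length(grid_spec()$beta) * 2 # 176 grid rows
grid_spec <- function(gamma = seq(1.2, 1.9, by = 0.1),
                      beta = seq(0.5, 3.0, by = 0.25),
                      families = c("power", "exponential"),
                      objective = c("srmse", "mae", "mape")) {
  if (length(gamma) == 0 || length(beta) == 0 || length(families) == 0) {
    abort_field("grid", "gamma, beta and families must be non-empty")
  }
  families <- match.arg(families, c("power", "exponential"), several.ok = TRUE)
  structure(
    list(
      gamma = gamma, beta = beta, families = families,
      objective = match.arg(objective)
    ),
    class = "grid_spec"
  )
}

#' Grid-search calibration of the gravity model
#'
#' Evaluates every (family, gamma, beta) combination against one
#' intercensal interval: derive growth-adjusted targets, scale the gravity
#' flows, project end populations and score them against the observed
#' census stocks with SRMSE, MAE and MAPE. The best row minimises the
#' objective; ties break towards smaller beta, then smaller gamma, then
#' power before exponential. Rows with non-finite metrics are flagged and
#' excluded from selection with a warning.
#'
#' Census stocks identify only net migration, so by default the scaling
#' constant is fixed per grid point by matching the predicted net-migration
#' volume `sum(max(0, net_i))` to the target volume `T` from
#' [derive_targets()] (`k_constraint = "net_volume"`). With
#' `k_constraint = "flow_total"` the gross predicted flows are forced to
#' sum to `T` instead (the [normalise_k()] convention); because `T` is a
#' net volume this shrinks predicted nets by a pattern-dependent factor and
#' is kept only for sensitivity analysis.
#'
#' @param settlements Settlement table with both wave columns.
#' @param distances A [dist_matrix()].
#' @param start_wave,end_wave Census wave labels of the interval.
#' @param grid A [grid_spec()].
#' @param k_constraint `"net_volume"` (default) or `"flow_total"`.
#' @return A tibble of class `calibration_result`, one row per grid point
#'   (`family`, `gamma`, `beta`, `k`, `total`, `srmse`, `mae`, `mape`,
#'   `best`), with the interval targets and selection rule in attributes.
#' @export
grid_search <- function(settlements, distances, start_wave, end_wave,
                        grid = grid_spec(),
                        k_constraint = c("net_volume", "flow_total")) {
  k_constraint <- match.arg(k_constraint)
  targets <- derive_targets(settlements, start_wave, end_wave)
  pop <- pop_vector(settlements, start_wave)
  observed_end <- pop_vector(settlements, end_wave)
  D <- as.matrix(distances)
  i <- align_ids(rownames(D), names(pop), "distance matrix")
  D <- D[i, i, drop = FALSE]
  off <- row(D) != col(D)
  g <- targets$growth_factor
  total <- targets$total

  pow_gamma <- lapply(grid$gamma, function(gm) pop^gm)
  names(pow_gamma) <- as.character(grid$gamma)

  rows <- purrr::map_dfr(grid$families, function(fam) {
    purrr::map_dfr(grid$beta, function(b) {
      W <- matrix(0, nrow(D), ncol(D))
      W[off] <- decay(D[off], b, fam)
      purrr::map_dfr(grid$gamma, function(gm) {
        B <- outer(pop, pow_gamma[[as.character(gm)]]) * W
        diag(B) <- 0
        net <- colSums(B) - rowSums(B)
        k <- if (total == 0) {
          0
        } else if (k_constraint == "net_volume") {
          pos <- sum(pmax(0, net))
          if (pos > 0) total / pos else NaN
        } else {
          total / sum(B)
        }
        projected <- pmax(g * pop + k * net, 0)
        tibble::tibble(
          family = fam, gamma = gm, beta = b, k = k, total = total,
          srmse = srmse(observed_end, projected),
          mae = mae(observed_end, projected),
          mape = as.numeric(mape(observed_end, projected))
        )
      })
    })
  })

  obj <- rows[[grid$objective]]
  finite <- is.finite(obj) & is.finite(rows$k)
  if (!all(finite)) {
    warn(sprintf("%d grid row(s) with non-finite metrics excluded from selection", sum(!finite)))
  }
  if (!any(finite)) abort("no finite grid rows to select from")
  ord <- order(!finite, obj, rows$beta, rows$gamma,
               match(rows$family, c("power", "exponential")))
  rows$best <- seq_len(nrow(rows)) == ord[1]
  structure(
    rows,
    class = c("calibration_result", class(rows)),
    targets = targets,
    interval = c(start_wave, end_wave),
    objective = grid$objective,
    k_constraint = k_constraint,
    selection = "min objective; ties: smaller beta, then gamma, then power first"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  iv <- attr(x, "interval")
  best <- dplyr::filter(x, .data$best)
  cat(sprintf(
    "<calibration_result> interval %s-%s: %d grid rows, objective %s\n",
    iv[1], iv[2], nrow(x), attr(x, "objective")
  ))
  cat(sprintf(
    "best: %s decay, gamma = %g, beta = %g (SRMSE %.4f, MAE %.2f, MAPE %.2f%%)\n",
    best$family, best$gamma, best$beta, best$srmse, best$mae, best$mape
  ))
  invisible(x)
}

#' @method tidy calibration_result
#' @export
tidy.calibration_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  best <- dplyr::filter(tibble::as_tibble(x), .data$best)
  targets <- attr(x, "targets")
  iv <- attr(x, "interval")
  tibble::tibble(
    interval = paste(iv, collapse = "-"),
    family = best$family, gamma = best$gamma, beta = best$beta,
    k = best$k, total = best$total,
    growth_factor = targets$growth_factor,
    srmse = best$srmse, mae = best$mae, mape = best$mape,
    objective = attr(x, "objective")
  )
}

#' Extract the best parameters from a calibration
#'
#' @param result A `calibration_result` from [grid_search()].
#' @return A [model_params()] with the calibrated `k`.
#' @export
best_params <- function(result) {
  best <- dplyr::filter(tibble::as_tibble(result), .data$best)
  model_params(best$family, beta = best$beta, gamma = best$gamma, k = best$k)
}
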