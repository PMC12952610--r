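#' Mean absolute error
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return `mean(|observed - predicted|)`, in the units of the inputs.
#' @export
#' @examples
#' mae(c(100, 200), c(110, 190)) # 10
mae <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort_field("predicted", "length mismatch with observed")
  }
  if (length(observed) == 0) abort_field("observed", "must be non-empty")
  mean(abs(observed - predicted))
}

#' Mean absolute percentage error
#'
#' Averages `|observed - predicted| / observed` over entries with a nonzero
#' observed value and reports the result in percent. Zero-observed entries
#' are excluded (MAPE is unstable near zero); their count is attached as
#' attribute `excluded`.
#'
#' @inheritParams mae
#' @return MAPE in percent, with attribute `excluded`.
#' @export
#' @examples
#' mape(c(100, 200), c(110, 190)) # 7.5
mape <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort_field("predicted", "length mismatch with observed")
  }
  keep <- observed != 0
  if (!any(keep)) abort_field("observed", "all observed values are zero")
  out <- 100 * mean(abs((observed[keep] - predicted[keep]) / observed[keep]))
  attr(out, "excluded") <- sum(!keep)
  out
}

#' Standardised root mean squared error
#'
#' RMSE divided by the mean observed value: a dimensionless, scale-free fit
#' statistic, comparable across intervals with different totals. The entry
#' set (flows or populations) is the caller's choice.
#'
#' @inheritParams mae
#' @return SRMSE (dimensionless).
#' @export
#' @examples
#' srmse(c(2, 2), c(4, 0)) # 1
srmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort_field("predicted", "length mismatch with observed")
  }
  mo <- mean(observed)
  if (!is.finite(mo) || mo <= 0) abort_field("observed", "mean observed must be > 0")
  sqrt(mean((observed - predicted)^2)) / mo
}

#' All three fit metrics at once
#'
#' @inheritParams mae
#' @param entry_set Label recording what the entries are (e.g.
#'   `"populations"` or `"flows"`).
#' @return One-row tibble with `srmse`, `mae`, `mape`, `n`, `n_excluded`,
#'   `entry_set`.
#' @export
fit_metrics <- function(observed, predicted, entry_set = "populations") {
  mp <- mape(observed, predicted)
  tibble::tibble(
    srmse = srmse(observed, predicted),
    mae = mae(observed, predicted),
    mape = as.numeric(mp),
    n = length(observed),
    n_excluded = attr(mp, "excluded"),
    entry_set = entry_set
  )
}

#' Aggregate settlement flows to regional totals
#'
#' Cell (a, b) is the sum of all flows from settlements in region `a` to
#' settlements in region `b`, including `a = b` (intra-region moves between
#' distinct settlements). The grand total equals the flow-matrix total
#' exactly for integer flows.
#'
#' @param flows A [flow_matrix()].
#' @param settlements Settlement table with a `region` column, or a named
#'   character vector mapping settlement id to region.
#' @return An R x R matrix with region dimnames.
#' @export
aggregate_regions <- function(flows, settlements) {
  m <- as.matrix(flows)
  region <- if (is.data.frame(settlements)) {
    setNames(settlements$region, settlements$id)
  } else {
    settlements
  }
  unmapped <- setdiff(rownames(m), names(region))
  if (length(unmapped) > 0) {
    abort_field("settlements", paste(
      "settlements without a region:",
      paste(head(unmapped, 5), collapse = ", ")
    ))
  }
  r <- region[rownames(m)]
  labels <- sort(unique(unname(r)))
  f <- factor(r, levels = labels)
  # sum rows within origin region, then columns within destination region
  byrow <- rowsum(m, f)
  t(rowsum(t(byrow), f))
}

#' Cellwise relative difference between two regional matrices
#'
#' `RD_ab = (predicted_ab - observed_ab) / observed_ab` wherever the
#' observed flow is positive; positive values indicate overestimation.
#' Where the observed flow is zero the cell is undefined (`NA`, printed as
#' a dash) by default; `mode = "epsilon"` instead divides by the small
#' stabiliser `epsilon`.
#'
#' @param predicted,observed Same-shaped nonnegative matrices with matching
#'   labels.
#' @param mode `"marker"` (default: zero-observed cells are `NA`) or
#'   `"epsilon"`.
#' @param epsilon Stabiliser used in `"epsilon"` mode (default 1e-9).
#' @return Matrix of relative differences.
#' @export
#' @examples
#' relative_difference(matrix(701), matrix(3154)) # -0.7777 -> prints as -0.78
relative_difference <- function(predicted, observed, mode = c("marker", "epsilon"),
                                epsilon = 1e-9) {
  mode <- match.arg(mode)
  predicted <- as.matrix(predicted)
  observed <- as.matrix(observed)
  if (!all(dim(predicted) == dim(observed))) {
    abort_field("observed", "shape mismatch with predicted")
  }
  if (!is.null(dimnames(predicted)) && !is.null(dimnames(observed)) &&
      !identical(dimnames(predicted), dimnames(observed))) {
    abort_field("observed", "label mismatch with predicted")
  }
  if (any(observed < 0)) abort_field("observed", "must be nonnegative")
  rd <- (predicted - observed) / observed
  zero <- observed == 0
  rd[zero] <- if (mode == "marker") NA_real_ else (predicted[zero] - 0) / epsilon
  rd
}

#' Regional benchmark comparison
#'
#' Builds the full benchmark panel: predicted and observed regional
#' matrices augmented with row, column and grand totals, and the relative
#' difference on every cell including the marginals. Totals default to the
#' cell sums but printed benchmark totals can be supplied (historical
#' tables often total unrounded values).
#'
#' @inheritParams relative_difference
#' @param predicted_totals,observed_totals Optional lists with `row`,
#'   `col`, `grand` overriding the computed marginals.
#' @return A list of class `regional_comparison` with `predicted`,
#'   `observed` and `rd` matrices (each R+1 x R+1, last row/col = totals),
#'   plus `epsilon` and `mode`.
#' @export
regional_comparison <- function(predicted, observed, mode = c("marker", "epsilon"),
                                epsilon = 1e-9,
                                predicted_totals = NULL, observed_totals = NULL) {
  mode <- match.arg(mode)
  pa <- add_marginals(predicted, predicted_totals)
  oa <- add_marginals(observed, observed_totals)
  structure(
    list(
      predicted = pa, observed = oa,
      rd = relative_difference(pa, oa, mode = mode, epsilon = epsilon),
      mode = mode, epsilon = epsilon
    ),
    class = "regional_comparison"
  )
}

add_marginals <- function(m, totals = NULL) {
  m <- as.matrix(m)
  rowt <- totals$row %||% rowSums(m)
  colt <- totals$col %||% colSums(m)
  grand <- totals$grand %||% sum(m)
  out <- rbind(cbind(m, Total = rowt), Total = c(colt, grand))
  out
}

#' @export
print.regional_comparison <- function(x, digits = 2, ...) {
  cat("<regional_comparison>\n\nPredicted flows\n")
  print(round(x$predicted, digits))
  cat("\nObserved flows\n")
  print(round(x$observed, digits))
  cat("\nRelative difference (– = undefined, observed flow is zero)\n")
  rd <- formatC(round(x$rd, digits), format = "f", digits = digits)
  rd[is.na(x$rd)] <- "–"
  print(rd, quote = FALSE)
  invisible(x)
}

#' @method tidy regional_comparison
#' @export
tidy.regional_comparison <- function(x, ...) {
  labs <- rownames(x$rd)
  tibble::tibble(
    origin = rep(labs, times = length(labs)),
    destination = rep(labs, each = length(labs)),
    predicted = as.vector(x$predicted),
    observed = as.vector(x$observed),
    rd = as.vector(x$rd)
  )
}
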