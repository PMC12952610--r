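#' DEM grid constructor
#'
#' A regular elevation raster in metres. Rows run top to bottom (row 1 is
#' the northernmost); the origin is the outer lower-left corner, in the same
#' planar-km convention as settlement coordinates.
#'
#' @param elev Numeric matrix of elevations in metres (`NA` = nodata).
#' @param cellsize_m Cell size in metres (> 0).
#' @param xll,yll Lower-left corner of the grid in km.
#' @param nodata Nodata marker used on disk (in memory nodata is `NA`).
#' @return A list of class `dem_grid`.
#' @export
dem_grid <- function(elev, cellsize_m, xll = 0, yll = 0, nodata = -9999) {
  if (!is.matrix(elev)) abort_field("elev", "must be a matrix")
  if (cellsize_m <= 0) abort_field("cellsize_m", "must be > 0")
  if (any(is.infinite(elev))) abort_field("elev", "elevations must be finite or NA")
  structure(
    list(
      elev = elev, cellsize_m = cellsize_m,
      xll = xll, yll = yll, nodata = nodata
    ),
    class = "dem_grid"
  )
}

#' @export
print.dem_grid <- function(x, ...) {
  cat(sprintf(
    "<dem_grid> %d x %d cells of %.0f m, elevation %.0f..%.0f m\n",
    nrow(x$elev), ncol(x$elev), x$cellsize_m,
    min(x$elev, na.rm = TRUE), max(x$elev, na.rm = TRUE)
  ))
  invisible(x)
}

# Cell-centre coordinates (km) for a dem_grid / tri_grid; row 1 = top.
dem_cell_centres <- function(dem) {
  cs <- dem$cellsize_m / 1000
  list(
    x = dem$xll + (seq_len(ncol(dem$elev)) - 0.5) * cs,
    y = dem$yll + (nrow(dem$elev) - seq_len(nrow(dem$elev)) + 0.5) * cs
  )
}

#' Terrain Ruggedness Index (Riley formulation)
#'
#' For every interior cell with all 8 neighbours valid,
#' `TRI = sqrt(sum over the 8 neighbours of (z_n - z_c)^2)`, in metres.
#' Border cells and cells with any nodata neighbour are nodata: partial
#' neighbourhoods would bias the index low. The index is invariant under
#' elevation translation and scales linearly with elevation scaling.
#'
#' @param dem A [dem_grid()] of at least 3 x 3 cells.
#' @return A `dem_grid` whose `elev` slot holds TRI values (metres).
#' @export
#' @examples
#' z <- matrix(0, 3, 3); z[2, 2] <- 1
#' tri(dem_grid(z, 30))$elev[2, 2] # sqrt(8)
tri <- function(dem) {
  z <- dem$elev
  if (nrow(z) < 3 || ncol(z) < 3) abort_field("dem", "grid must be at least 3x3 for TRI")
  if (all(is.na(z))) abort_field("dem", "all-nodata grid")
  nr <- nrow(z)
  nc <- ncol(z)
  acc <- matrix(0, nr - 2, nc - 2)
  ok <- !is.na(z[2:(nr - 1), 2:(nc - 1)])
  centre <- z[2:(nr - 1), 2:(nc - 1)]
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- z[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
      ok <- ok & !is.na(nb)
      acc <- acc + (nb - centre)^2
    }
  }
  out <- matrix(NA_real_, nr, nc)
  inner <- sqrt(acc)
  inner[!ok] <- NA_real_
  out[2:(nr - 1), 2:(nc - 1)] <- inner
  dem_grid(out, dem$cellsize_m, dem$xll, dem$yll, dem$nodata)
}

#' Mean TRI per settlement within a circular buffer
#'
#' Averages valid TRI cells whose centres lie within `radius_km` of each
#' settlement point. A settlement whose buffer contains no valid cell falls
#' back to the nearest valid cell (with a note); a settlement outside the
#' raster extent entirely is an error.
#'
#' @param tri_grid TRI raster from [tri()].
#' @param settlements Settlement table in the same planar-km frame.
#' @param radius_km Buffer radius in km (default 2).
#' @return Tibble with `id` and `mean_tri_m`.
#' @export
settlement_tri <- function(tri_grid, settlements, radius_km = 2) {
  validate_settlements(settlements)
  if (radius_km <= 0) abort_field("radius_km", "must be > 0")
  cc <- dem_cell_centres(tri_grid)
  cs <- tri_grid$cellsize_m / 1000
  xmax <- tri_grid$xll + ncol(tri_grid$elev) * cs
  ymax <- tri_grid$yll + nrow(tri_grid$elev) * cs
  outside <- settlements$x < tri_grid$xll | settlements$x > xmax |
    settlements$y < tri_grid$yll | settlements$y > ymax
  if (any(outside)) {
    abort_field("settlements", paste(
      "outside raster extent:",
      paste(head(settlements$id[outside], 5), collapse = ", ")
    ))
  }
  fallbacks <- 0L
  means <- purrr::map_dbl(seq_len(nrow(settlements)), function(i) {
    dx2 <- (cc$x - settlements$x[i])^2
    dy2 <- (cc$y - settlements$y[i])^2
    cols <- which(dx2 <= radius_km^2)
    rows <- which(dy2 <= radius_km^2)
    vals <- numeric(0)
    if (length(rows) > 0 && length(cols) > 0) {
      sub <- tri_grid$elev[rows, cols, drop = FALSE]
      within <- outer(dy2[rows], dx2[cols], "+") <= radius_km^2
      vals <- sub[within & !is.na(sub)]
    }
    if (length(vals) > 0) {
      return(mean(vals))
    }
    # fall back to nearest valid cell
    fallbacks <<- fallbacks + 1L
    valid <- which(!is.na(tri_grid$elev), arr.ind = TRUE)
    if (nrow(valid) == 0) abort_field("tri_grid", "no valid TRI cells")
    dd <- (cc$y[valid[, 1]] - settlements$y[i])^2 + (cc$x[valid[, 2]] - settlements$x[i])^2
    tri_grid$elev[valid[which.min(dd), , drop = FALSE]]
  })
  if (fallbacks > 0) {
    inform(sprintf("%d settlement(s) had no valid TRI cell in buffer; nearest cell used", fallbacks))
  }
  tibble::tibble(id = settlements$id, mean_tri_m = means)
}

#' Quantile group classification
#'
#' Ranks values ascending (ties broken by id for determinism) and assigns
#' group `ceiling(k * rank / n)`; group `k` is the most rugged. Group sizes
#' differ by at most one when values are distinct, and the grouping is
#' monotone in the value.
#'
#' @param values Numeric vector (e.g. mean TRI per settlement).
#' @param ids Ids used for deterministic tie-breaking (defaults to names of
#'   `values`, else index order).
#' @param k Number of groups (default 5).
#' @return Integer vector of group labels 1..k, in input order.
#' @export
#' @examples
#' quantile_groups(c(a = 10, b = 30, c = 20, d = 40), k = 2) # 1 2 1 2
quantile_groups <- function(values, ids = NULL, k = 5) {
  if (length(values) == 0) abort_field("values", "must be non-empty")
  if (k < 2) abort_field("k", "must be >= 2")
  n <- length(values)
  if (n < k) abort_field("values", sprintf("need at least k = %d values, got %d", k, n))
  ids <- ids %||% names(values) %||% as.character(seq_len(n))
  if (length(unique(values)) == 1L) {
    warn("all values equal: quantile groups assigned by id order")
  }
  ord <- order(values, ids)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  as.integer(ceiling(k * rank / n))
}

#' Ruggedness table: mean TRI and quantile group per settlement
#'
#' Convenience wrapper chaining [settlement_tri()] and [quantile_groups()].
#'
#' @inheritParams settlement_tri
#' @param k Number of quantile groups.
#' @return Tibble with `id`, `mean_tri_m`, `tri_group` (k = most rugged).
#' @export
ruggedness_table <- function(tri_grid, settlements, radius_km = 2, k = 5) {
  out <- settlement_tri(tri_grid, settlements, radius_km)
  out$tri_group <- quantile_groups(out$mean_tri_m, ids = out$id, k = k)
  out
}
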