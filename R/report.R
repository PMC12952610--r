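#' Thresholded flow network
#'
#' Keeps directed edges with flow strictly above the threshold (default 1
#' migrant, the conventional noise cut) while node-level inflow, outflow
#' and net are computed from the unthresholded matrix, so node attributes
#' remain conserved quantities.
#'
#' @param flows A [flow_matrix()].
#' @param settlements Optional settlement table supplying node coordinates.
#' @param threshold Strict lower bound on retained edge flows.
#' @return A list of class `flow_network` with `nodes` (id, x, y, inflow,
#'   outflow, net) and `edges` (origin, destination, flow) tibbles.
#' @export
export_flow_network <- function(flows, settlements = NULL, threshold = 1) {
  s <- flow_summary(flows)
  nodes <- s
  if (!is.null(settlements)) {
    nodes <- dplyr::left_join(
      s, dplyr::select(settlements, "id", "x", "y"),
      by = "id"
    ) |> dplyr::relocate("x", "y", .after = "id")
  }
  edges <- flows_to_long(flows) |> dplyr::filter(.data$flow > threshold)
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
    class = "flow_network"
  )
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf(
    "<flow_network> %d nodes, %d edges with flow > %g\n",
    nrow(x$nodes), nrow(x$edges), x$threshold
  ))
  invisible(x)
}

# Adjusted Fisher-Pearson sample skewness (the b_1 moment estimator with
# the small-sample correction factor sqrt(n(n-1))/(n-2)).
skewness_adj <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(0)
  g1 <- mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Distributions of settlement-level migration measures
#'
#' Bins inflow, outflow and net migration per interval. Log histograms use
#' log10 bins of width 0.25 anchored at the smallest positive value (zeros
#' and, for net migration, negatives are counted separately); linear
#' histograms use `n_linear_bins` equal-width bins over the observed range.
#' The adjusted Fisher-Pearson sample skewness is reported per measure.
#'
#' @param summaries A migration summary tibble from [flow_summary()], or a
#'   named list of them (names = interval labels).
#' @param n_linear_bins Number of equal-width linear bins (default 20).
#' @return A list with `log_bins`, `linear_bins` and `skewness` tibbles.
#' @export
flow_distributions <- function(summaries, n_linear_bins = 20) {
  if (is.data.frame(summaries)) summaries <- list(interval = summaries)
  if (length(summaries) == 0) abort_field("summaries", "must contain at least one interval")
  measures <- c("inflow", "outflow", "net")

  per <- purrr::imap(summaries, function(s, label) {
    purrr::map(measures, function(msr) {
      x <- s[[msr]]
      pos <- x[x > 0]
      logb <- if (length(pos) > 0) {
        lo <- floor(log10(min(pos)) / 0.25) * 0.25
        nbin <- floor((log10(max(pos)) - lo) / 0.25) + 1
        breaks <- lo + 0.25 * (0:nbin)
        cnt <- table(cut(log10(pos), breaks = breaks, right = FALSE))
        tibble::tibble(
          interval = label, measure = msr, scale = "log10",
          bin_lo = 10^breaks[-length(breaks)], bin_hi = 10^breaks[-1],
          count = as.integer(cnt)
        )
      } else {
        tibble::tibble(
          interval = character(), measure = character(), scale = character(),
          bin_lo = numeric(), bin_hi = numeric(), count = integer()
        )
      }
      rng <- range(x)
      breaks <- if (rng[1] == rng[2]) {
        c(rng[1] - 0.5, rng[1] + 0.5)
      } else {
        seq(rng[1], rng[2], length.out = n_linear_bins + 1)
      }
      cnt <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
      linb <- tibble::tibble(
        interval = label, measure = msr, scale = "linear",
        bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
        count = as.integer(cnt)
      )
      sk <- tibble::tibble(
        interval = label, measure = msr,
        skewness = skewness_adj(x),
        n = length(x), n_zero = sum(x == 0), n_negative = sum(x < 0)
      )
      list(log = logb, linear = linb, skew = sk)
    })
  })
  flat <- purrr::flatten(per)
  list(
    log_bins = purrr::map_dfr(flat, "log"),
    linear_bins = purrr::map_dfr(flat, "linear"),
    skewness = purrr::map_dfr(flat, "skew")
  )
}

#' Net-migration box statistics per TRI quantile group
#'
#' For each interval and ruggedness group: median, quartiles, 5th and 95th
#' percentiles (linear interpolation between order statistics), mean and
#' group size of net migration. With `per_capita = TRUE` net migration is
#' divided by the start population first.
#'
#' @param ruggedness Tibble with `id` and `tri_group` (see
#'   [ruggedness_table()]).
#' @param summaries A migration summary tibble or named list of them.
#' @param per_capita Divide net by start population (requires `start_pop`
#'   column in the summaries).
#' @return Tibble of class `group_box_stats`, one row per interval x group.
#' @export
tri_migration_stats <- function(ruggedness, summaries, per_capita = FALSE) {
  if (is.data.frame(summaries)) summaries <- list(interval = summaries)
  out <- purrr::imap_dfr(summaries, function(s, label) {
    missing_ids <- setdiff(s$id, ruggedness$id)
    if (length(missing_ids) > 0) {
      abort_field("ruggedness", paste(
        "settlements without a TRI group:",
        paste(head(missing_ids, 5), collapse = ", ")
      ))
    }
    df <- dplyr::inner_join(s, ruggedness[c("id", "tri_group")], by = "id")
    if (per_capita) {
      if (!"start_pop" %in% names(df)) {
        abort_field("summaries", "per_capita = TRUE requires a start_pop column")
      }
      df$net <- df$net / df$start_pop
    }
    df |>
      dplyr::group_by(.data$tri_group) |>
      dplyr::summarise(
        interval = label,
        p5 = quantile(.data$net, 0.05, names = FALSE),
        q1 = quantile(.data$net, 0.25, names = FALSE),
        median = median(.data$net),
        q3 = quantile(.data$net, 0.75, names = FALSE),
        p95 = quantile(.data$net, 0.95, names = FALSE),
        mean = mean(.data$net),
        n = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::relocate("interval")
  })
  structure(out, class = c("group_box_stats", class(out)))
}

#' Top destinations of migrants from the most rugged settlements
#'
#' Sums all flows originating in the highest TRI quantile group by
#' destination (destinations in the top group are themselves eligible) and
#' returns the top `k` destinations; ties break by destination id.
#'
#' @param flows A [flow_matrix()].
#' @param ruggedness Tibble with `id` and `tri_group`.
#' @param k Number of destinations to return (default 10).
#' @param group Origin group treated as "most rugged" (default: the
#'   maximum group present).
#' @return Tibble with `destination`, `flow`, `rank`.
#' @export
top_destinations <- function(flows, ruggedness, k = 10, group = NULL) {
  if (k < 1) abort_field("k", "must be >= 1")
  group <- group %||% max(ruggedness$tri_group)
  origins <- ruggedness$id[ruggedness$tri_group == group]
  if (length(origins) == 0) abort_field("ruggedness", "most-rugged group is empty")
  m <- as.matrix(flows)
  origins <- intersect(origins, rownames(m))
  totals <- colSums(m[origins, , drop = FALSE])
  df <- tibble::tibble(destination = names(totals), flow = unname(totals)) |>
    dplyr::arrange(dplyr::desc(.data$flow), .data$destination) |>
    head(k)
  df$rank <- seq_len(nrow(df))
  df
}
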