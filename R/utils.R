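# Internal helpers: validation, seed substreams, population extraction.

# Deterministic sub-seed for a named random substream, so regenerating one
# layer (settlements / dem / roads / flows) never perturbs the others.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 1009)
  as.integer((as.numeric(seed) + h) %% 2147483629)
}

with_substream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}

abort_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "gravityflow_validation_error")
}

check_positive_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    abort_field(field, "must be a single integer >= 1")
  }
  invisible(as.integer(x))
}

# Population column names follow the pattern pop_<wave label>.
pop_columns <- function(settlements) {
  nm <- names(settlements)
  nm[startsWith(nm, "pop_")]
}

wave_labels <- function(settlements) {
  sub("^pop_", "", pop_columns(settlements))
}

# Named population vector for one census wave. `wave` may be a bare label
# ("1934") or a full column name ("pop_1934"); NULL picks the first wave.
pop_vector <- function(settlements, wave = NULL) {
  cols <- pop_columns(settlements)
  if (length(cols) == 0L) abort_field("settlements", "no pop_<wave> columns found")
  col <- if (is.null(wave)) {
    cols[[1L]]
  } else if (wave %in% cols) {
    wave
  } else {
    paste0("pop_", wave)
  }
  if (!col %in% cols) {
    abort_field("wave", sprintf("no column `%s` in settlements", col))
  }
  setNames(as.numeric(settlements[[col]]), settlements$id)
}

validate_settlements <- function(settlements) {
  req <- c("id", "x", "y")
  missing_cols <- setdiff(req, names(settlements))
  if (length(missing_cols) > 0L) {
    abort_field("settlements", paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(settlements$id)) {
    dup <- unique(settlements$id[duplicated(settlements$id)])
    abort_field("id", paste("duplicated settlement ids:", paste(dup, collapse = ", ")))
  }
  invisible(settlements)
}

settlement_coords <- function(settlements, coords = NULL) {
  coords <- coords %||% attr(settlements, "coords") %||% "planar_km"
  match.arg(coords, c("planar_km", "lonlat"))
}

# Align a named vector or keyed tibble to a reference id ordering.
align_ids <- function(ids, ref_ids, what) {
  if (!setequal(ids, ref_ids) || length(ids) != length(ref_ids)) {
    abort(sprintf("%s ids do not match settlement ids", what),
      class = "gravityflow_validation_error"
    )
  }
  match(ref_ids, ids)
}
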