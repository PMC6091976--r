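#' Activity maps: sectors-by-time matrices of edge dynamics or signaling
#'
#' An `activity_map` is the central tabular container of the package: a
#' numeric matrix whose rows are ~3 um sectors along the cell boundary and
#' whose columns are time points. Entries hold either signed normal edge
#' velocities (um/min, protrusion positive) or a windowed biosensor signal.
#' Velocity maps derived from frame pairs have `n_frames - 1` columns and
#' column times at the frame-pair midpoints.
#'
#' @param x numeric matrix, rows = sectors, columns = time points.
#' @param dt frame interval in seconds.
#' @param units character, e.g. `"um/min"` or `"a.u."`.
#' @param times optional numeric vector of column times in seconds.
#' @param counts optional integer matrix of per-entry sample counts.
#'
#' @return An `activity_map` object (numeric matrix with metadata
#'   attributes `dt`, `units`, `times`, `counts`).
#' @export
activity_map <- function(x, dt, units = "um/min", times = NULL, counts = NULL) {
  x <- as.matrix(x)
  stopifnot_scalar(dt, "dt")
  if (is.null(times)) times <- (seq_len(ncol(x)) - 1) * dt
  if (length(times) != ncol(x)) abort("`times` must have one entry per column")
  if (!is.null(counts) && !all(dim(counts) == dim(x))) {
    abort("`counts` must match the dimensions of `x`")
  }
  structure(x,
    dt = dt, units = units, times = as.numeric(times), counts = counts,
    class = c("activity_map", "matrix", "array")
  )
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf(
    "<activity_map> %d sectors x %d time points, dt = %gs, units = %s\n",
    nrow(x), ncol(x), attr(x, "dt"), attr(x, "units")
  ))
  cat(sprintf(
    "  value range: [%.3g, %.3g], %d missing\n",
    suppressWarnings(min(x, na.rm = TRUE)),
    suppressWarnings(max(x, na.rm = TRUE)), sum(is.na(x))
  ))
  invisible(x)
}

#' Tidy an activity map into a long tibble
#'
#' @param x an [activity_map].
#' @param ... unused.
#' @return A tibble with columns `sector`, `frame`, `time` (seconds),
#'   `value`, and `n` (sample count, `NA` when not recorded).
#' @export
tidy.activity_map <- function(x, ...) {
  counts <- attr(x, "counts")
  out <- tibble(
    sector = rep(seq_len(nrow(x)), times = ncol(x)),
    frame = rep(seq_len(ncol(x)), each = nrow(x)),
    time = rep(attr(x, "times"), each = nrow(x)),
    value = as.vector(unclass(x))
  )
  out$n <- if (is.null(counts)) NA_integer_ else as.vector(counts)
  out
}

#' @export
glance.activity_map <- function(x, ...) {
  tibble(
    n_sectors = nrow(x), n_frames = ncol(x), dt = attr(x, "dt"),
    units = attr(x, "units"),
    mean_abs_value = mean(abs(x), na.rm = TRUE),
    n_missing = sum(is.na(x))
  )
}

#' @export
autoplot.activity_map <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$time / 60, y = .data$sector, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = attr(object, "units")) +
    labs(x = "time (min)", y = "sector") +
    theme_bw()
}

#' Write / read an activity map as CSV with a JSON sidecar
#'
#' The matrix is written as a plain CSV (rows = sectors); metadata (`dt`,
#' `units`, column times) goes to `<path>.json`.
#'
#' @param map an [activity_map].
#' @param path CSV file path.
#' @return `path`, invisibly (`write_activity_map`); an [activity_map]
#'   (`read_activity_map`).
#' @export
write_activity_map <- function(map, path) {
  write.csv(as.data.frame(unclass(map)), path, row.names = FALSE)
  meta <- list(
    dt = attr(map, "dt"), units = attr(map, "units"),
    times = attr(map, "times"), n_sectors = nrow(map), n_frames = ncol(map)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_activity_map
#' @export
read_activity_map <- function(path) {
  m <- as.matrix(read.csv(path, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  activity_map(m, dt = meta$dt, units = meta$units, times = meta$times)
}
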