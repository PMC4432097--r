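#' Parse a spectrum series from JSON
#'
#' Reads one data series from JSON text. Two equivalent schemas are accepted:
#' a pair-list form `{"name": "s1", "points": [[x, y], ...]}` and a
#' parallel-array form `{"name": "s1", "x": [...], "y": [...]}`. The `name`
#' field is optional in both; a series left unnamed receives a computed
#' identifier `series-<k>` when it is added to a dataset. For
#' `kind = "points2d"` (2D NMR cross peaks) each point may carry a third
#' value (intensity), either as a triple `[x, y, value]` or a parallel
#' `"value"` array.
#'
#' Points are sorted ascending by x on ingestion; the original order is not
#' preserved. Binning and line rendering require monotone x.
#'
#' @param json_text JSON text (a single string) or a path to a JSON file.
#' @param kind Series kind: `"peaks"` (discrete peak list, e.g. a mass
#'   spectrum), `"trace"` (continuous x/y trace, e.g. 1D NMR or IR), or
#'   `"points2d"` (2D NMR point set).
#' @return An object of class `st_series`: a list with `name` (string or
#'   `NULL`), `points` (data frame with columns `x`, `y`, and `value` for
#'   2D point sets), `color` (string or `NULL`) and `kind`.
#' @export
#' @examples
#' s <- parse_series('{"name":"s1","points":[[2,1],[1,5]]}', "peaks")
#' s$points  # sorted ascending by x
parse_series <- function(json_text, kind = c("peaks", "trace", "points2d")) {
  kind <- match.arg(kind)
  if (length(json_text) != 1L || !is.character(json_text))
    st_value_error("json_text must be a single string")
  txt <- json_text
  if (!grepl("[{\\[]", substr(trimws(txt), 1L, 1L)) && file.exists(txt))
    txt <- paste(readLines(txt, warn = FALSE), collapse = "\n")
  obj <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyMatrix = TRUE),
    error = function(e) st_parse_error(paste0("JSON parse error: ", conditionMessage(e)))
  )
  if (!is.list(obj)) st_schema_error("series JSON must be an object")

  want_value <- identical(kind, "points2d")
  if (!is.null(obj$points)) {
    pts <- obj$points
    if (length(pts) == 0L) {
      df <- data.frame(x = numeric(0), y = numeric(0))
      if (want_value) df$value <- numeric(0)
    } else {
      if (!is.matrix(pts))
        st_schema_error("'points' must be an array of equal-length [x, y] pairs")
      nc <- ncol(pts)
      if (nc < 2L || nc > 3L)
        st_schema_error("'points' rows must have 2 (or 3, for 2D point sets) values")
      df <- data.frame(x = suppressWarnings(as.numeric(pts[, 1L])),
                       y = suppressWarnings(as.numeric(pts[, 2L])))
      if (want_value)
        df$value <- if (nc == 3L) suppressWarnings(as.numeric(pts[, 3L])) else NA_real_
    }
  } else if (!is.null(obj$x) || !is.null(obj$y)) {
    if (is.null(obj$x) || is.null(obj$y))
      st_schema_error("parallel-array form requires both 'x' and 'y'")
    xs <- suppressWarnings(as.numeric(obj$x))
    ys <- suppressWarnings(as.numeric(obj$y))
    if (length(xs) != length(ys))
      st_schema_error(sprintf("ragged parallel arrays: length(x)=%d, length(y)=%d",
                              length(xs), length(ys)))
    df <- data.frame(x = xs, y = ys)
    if (want_value) {
      if (!is.null(obj$value)) {
        vs <- suppressWarnings(as.numeric(obj$value))
        if (length(vs) != length(xs))
          st_schema_error(sprintf("ragged parallel arrays: length(value)=%d, length(x)=%d",
                                  length(vs), length(xs)))
        df$value <- vs
      } else df$value <- NA_real_
    }
  } else {
    st_schema_error("series JSON must contain 'points' or parallel 'x'/'y' arrays")
  }

  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad))
    st_value_error(sprintf("non-finite coordinate at point index %d", bad[1L]))

  ord <- order(df$x)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  name <- if (!is.null(obj$name) && nzchar(obj$name[1L])) as.character(obj$name[1L]) else NULL
  color <- if (!is.null(obj$color)) as.character(obj$color[1L]) else NULL
  new_series(name = name, points = df, color = color, kind = kind)
}

new_series <- function(name, points, color = NULL, kind = "peaks") {
  structure(list(name = name, points = points, color = color, kind = kind),
            class = "st_series")
}

#' Serialize a series back to JSON
#'
#' Inverse of [parse_series()] for the pair-list schema; `parse_series()`
#' composed with `serialize_series()` is the identity on point lists.
#'
#' @param s An `st_series` object.
#' @return JSON text (single string).
#' @export
serialize_series <- function(s) {
  stopifnot(inherits(s, "st_series"))
  cols <- if (identical(s$kind, "points2d") && !all(is.na(s$points$value)))
    c("x", "y", "value") else c("x", "y")
  m <- as.matrix(s$points[, cols, drop = FALSE])
  dimnames(m) <- NULL
  obj <- list()
  if (!is.null(s$name)) obj$name <- jsonlite::unbox(s$name)
  if (!is.null(s$color)) obj$color <- jsonlite::unbox(s$color)
  obj$points <- m
  as.character(jsonlite::toJSON(obj, digits = NA))
}

#' Create an empty dataset (data handler state)
#'
#' A dataset holds the series bound to a chart, its binning configuration and
#' the running x/y extents. All chart-data interaction goes through a
#' dataset: series are added with [add_series()] and removed with
#' [remove_series()]; at most one dataset is bound per chart.
#'
#' @param bin A bin configuration from [bin_config()].
#' @return An object of class `st_dataset`.
#' @export
new_dataset <- function(bin = bin_config()) {
  structure(list(series = list(), bin = bin, counter = 0L,
                 x_extent = NULL, y_extent = NULL),
            class = "st_dataset")
}

#' Binning configuration
#'
#' @param enabled Whether per-pixel binning is applied at render time.
#'   Binning can be turned off entirely, in which case every point of every
#'   series is rendered.
#' @param binwidth_px Bin width in pixels (positive integer, default 1).
#'   One pixel typically provides enough resolution to show the shape of a
#'   trace. The bin *mode* (minimum vs maximum intensity) is not configured
#'   here: the chart type dictates it.
#' @return A list with class `st_bin_config`.
#' @export
bin_config <- function(enabled = TRUE, binwidth_px = 1L) {
  binwidth_px <- as.integer(binwidth_px)
  if (is.na(binwidth_px) || binwidth_px < 1L)
    st_value_error("binwidth_px must be a positive integer")
  structure(list(enabled = isTRUE(enabled), binwidth_px = binwidth_px),
            class = "st_bin_config")
}

recompute_extents <- function(ds) {
  if (length(ds$series) == 0L) {
    ds$x_extent <- NULL
    ds$y_extent <- NULL
    return(ds)
  }
  xs <- unlist(lapply(ds$series, function(s) range(s$points$x)), use.names = FALSE)
  ys <- unlist(lapply(ds$series, function(s) range(s$points$y)), use.names = FALSE)
  xs <- xs[is.finite(xs)]; ys <- ys[is.finite(ys)]
  ds$x_extent <- if (length(xs)) range(xs) else NULL
  ds$y_extent <- if (length(ys)) range(ys) else NULL
  ds
}

#' Add a series to a dataset
#'
#' Appends a series and recomputes the dataset extents. An unnamed series is
#' assigned the computed identifier `series-<k>` where `k` is a per-dataset
#' running counter, so identifier assignment is deterministic given the add
#' order.
#'
#' @param ds An `st_dataset`.
#' @param s An `st_series`.
#' @return The updated dataset.
#' @export
add_series <- function(ds, s) {
  stopifnot(inherits(ds, "st_dataset"), inherits(s, "st_series"))
  ds$counter <- ds$counter + 1L
  if (is.null(s$name)) s$name <- sprintf("series-%d", ds$counter)
  if (s$name %in% names(ds$series))
    st_conflict_error(sprintf("series name '%s' already present in dataset", s$name))
  ds$series[[s$name]] <- s
  recompute_extents(ds)
}

#' Remove a series from a dataset by name
#'
#' @param ds An `st_dataset`.
#' @param name Name of the series to remove.
#' @return The updated dataset with extents recomputed from the remaining
#'   series; removing the last series yields empty (NULL) extents.
#' @export
remove_series <- function(ds, name) {
  stopifnot(inherits(ds, "st_dataset"))
  if (!name %in% names(ds$series))
    st_notfound_error(sprintf("no series named '%s' in dataset", name))
  ds$series[[name]] <- NULL
  recompute_extents(ds)
}

#' @export
print.st_dataset <- function(x, ...) {
  cat(sprintf("<st_dataset> %d series", length(x$series)))
  if (!is.null(x$x_extent))
    cat(sprintf(", x [%g, %g], y [%g, %g]",
                x$x_extent[1], x$x_extent[2], x$y_extent[1], x$y_extent[2]))
  cat("\n")
  for (s in x$series)
    cat(sprintf("  %s: %d points (%s)\n", s$name, nrow(s$points), s$kind))
  invisible(x)
}

#' @export
print.st_series <- function(x, ...) {
  cat(sprintf("<st_series> %s: %d points (%s)\n",
              if (is.null(x$name)) "<unnamed>" else x$name, nrow(x$points), x$kind))
  invisible(x)
}
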