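#' Chart-type registry
#'
#' Returns the immutable specification of one of the five pre-defined chart
#' types, encoding each spectroscopy's de facto layout standard:
#'
#' * `ms` — mass spectrum: impulse plot (one vertical line per peak from the
#'   zero baseline), m/z ascending, max-binning, box view windows.
#' * `nmr1d` — 1D NMR: line trace, chemical shift (ppm) REVERSED so high ppm
#'   sits on the left, max-binning (peaks point up), range view windows
#'   (x only; y rescales to the visible data).
#' * `nmr2d` — 2D NMR (e.g. HSQC): cross-peak point plot, BOTH ppm axes
#'   reversed, no binning.
#' * `ir` — infrared: line trace, wavenumber REVERSED (high cm-1 left),
#'   MIN-binning so transmittance absorption valleys are preserved, box
#'   view windows.
#' * `timeseries` — general time series: line, both axes ascending,
#'   max-binning, box view windows.
#'
#' @param type_id One of `"ms"`, `"nmr1d"`, `"nmr2d"`, `"ir"`,
#'   `"timeseries"`.
#' @return An object of class `st_chart_spec` with fields `type_id`,
#'   `x_reversed`, `y_reversed`, `render_style` (impulse/line/point),
#'   `bin_mode` (min/max/none), `zoom_semantics` (box/range),
#'   `x_label_default`, `y_label_default` and `precision` (decimals used for
#'   tick and signal labels).
#' @export
#' @examples
#' chart_spec("ms")$render_style   # "impulse"
#' chart_spec("ir")$bin_mode       # "min"
chart_spec <- function(type_id) {
  reg <- list(
    ms = list(type_id = "ms", x_reversed = FALSE, y_reversed = FALSE,
              render_style = "impulse", bin_mode = "max", zoom_semantics = "box",
              x_label_default = "m/z", y_label_default = "Intensity",
              precision = 2L),
    nmr1d = list(type_id = "nmr1d", x_reversed = TRUE, y_reversed = FALSE,
                 render_style = "line", bin_mode = "max", zoom_semantics = "range",
                 x_label_default = "Chemical shift [ppm]",
                 y_label_default = "Intensity", precision = 2L),
    nmr2d = list(type_id = "nmr2d", x_reversed = TRUE, y_reversed = TRUE,
                 render_style = "point", bin_mode = "none", zoom_semantics = "box",
                 x_label_default = "F2 [ppm]", y_label_default = "F1 [ppm]",
                 precision = 2L),
    ir = list(type_id = "ir", x_reversed = TRUE, y_reversed = FALSE,
              render_style = "line", bin_mode = "min", zoom_semantics = "box",
              x_label_default = "Wavenumber [1/cm]",
              y_label_default = "Transmittance", precision = 0L),
    timeseries = list(type_id = "timeseries", x_reversed = FALSE, y_reversed = FALSE,
                      render_style = "line", bin_mode = "max", zoom_semantics = "box",
                      x_label_default = "Time", y_label_default = "Amplitude",
                      precision = 2L)
  )
  if (length(type_id) != 1L || !type_id %in% names(reg))
    st_value_error(sprintf("unknown chart type '%s' (expected one of %s)",
                           paste(type_id, collapse = ","),
                           paste(names(reg), collapse = ", ")))
  structure(reg[[type_id]], class = "st_chart_spec")
}

#' Chart options
#'
#' Presentation options set at chart creation: title, axis labels, legend,
#' margins, signal labels, pixel size, a static view window (the offline
#' analogue of interactive zooming; omitting it shows the full data, the
#' analogue of a zoom reset) and an optional highlighted series (all other
#' series are dimmed, the static analogue of highlighting via a legend key).
#'
#' @param title Chart title (empty for none).
#' @param x_label,y_label Axis labels; `NULL` uses the chart type's default.
#' @param legend Draw a legend box (upper right) with one entry per series.
#' @param margins Named numeric vector `c(top, right, bottom, left)` in
#'   pixels; must leave a positive plot area.
#' @param signal_labels Label prominent local maxima with their x values.
#' @param max_labels Maximum number of signal labels per series.
#' @param width_px,height_px Total SVG size in pixels.
#' @param view_window `NULL` for the full data, or a list with `x = c(lo, hi)`
#'   and, for box-zoom chart types, optionally `y = c(lo, hi)`.
#' @param highlight Name of a series to highlight, or `NULL`.
#' @return An object of class `st_chart_options`.
#' @export
chart_options <- function(title = "", x_label = NULL, y_label = NULL,
                          legend = FALSE,
                          margins = c(top = 40, right = 30, bottom = 48, left = 64),
                          signal_labels = FALSE, max_labels = 5L,
                          width_px = 800L, height_px = 400L,
                          view_window = NULL, highlight = NULL) {
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (is.na(width_px) || width_px < 1L || is.na(height_px) || height_px < 1L)
    st_value_error("width_px and height_px must be positive integers")
  if (length(margins) != 4L || any(!is.finite(margins)) || any(margins < 0))
    st_value_error("margins must be four non-negative pixel lengths")
  names(margins) <- c("top", "right", "bottom", "left")
  structure(list(title = title, x_label = x_label, y_label = y_label,
                 legend = isTRUE(legend), margins = margins,
                 signal_labels = isTRUE(signal_labels),
                 max_labels = as.integer(max_labels),
                 width_px = width_px, height_px = height_px,
                 view_window = view_window, highlight = highlight),
            class = "st_chart_options")
}

#' Resolve the rendered view window
#'
#' Determines the x and y intervals shown by a chart. With no view window the
#' full data extents are used, the y side padded by 5% of its span — except
#' that a mass spectrum's zero baseline is never padded away. Range-zoom
#' chart types (1D NMR) accept an x-only window and rescale y to the data
#' visible inside it; box-zoom types accept explicit x and y windows. When
#' an x window is given without a y window, y is likewise recomputed from
#' the visible points.
#'
#' @param spec An `st_chart_spec`.
#' @param options An `st_chart_options`.
#' @param ds An `st_dataset`.
#' @return A list with elements `x` and `y`, each `c(lo, hi)`.
#' @export
resolve_view <- function(spec, options, ds) {
  vw <- options$view_window
  check_iv <- function(iv, what) {
    if (length(iv) != 2L || !all(is.finite(iv)) || iv[1L] >= iv[2L])
      st_value_error(sprintf("%s window must be a finite interval with lo < hi", what))
    as.numeric(iv)
  }
  full_x <- if (is.null(ds$x_extent)) c(0, 1) else pad_degenerate(ds$x_extent)
  xw <- if (!is.null(vw$x)) check_iv(vw$x, "x") else full_x

  if (!is.null(vw$y)) {
    if (identical(spec$zoom_semantics, "range"))
      st_value_error("range-zoom chart types accept x-only view windows")
    yw <- check_iv(vw$y, "y")
  } else {
    ys <- visible_y(ds, xw)
    yw <- pad_y(ys, spec)
  }
  list(x = xw, y = yw)
}

visible_y <- function(ds, xw) {
  ys <- unlist(lapply(ds$series, function(s) {
    p <- s$points
    inside <- p$x >= xw[1L] & p$x <= xw[2L]
    if (any(inside)) range(p$y[inside]) else numeric(0)
  }), use.names = FALSE)
  if (length(ys)) range(ys) else c(0, 1)
}

pad_y <- function(ys, spec) {
  if (identical(spec$type_id, "ms")) ys[1L] <- min(0, ys[1L])
  span <- ys[2L] - ys[1L]
  if (span == 0) span <- max(abs(ys[2L]), 1)
  pad <- 0.05 * span
  lo <- if (identical(spec$type_id, "ms")) ys[1L] else ys[1L] - pad
  c(lo, ys[2L] + pad)
}

pad_degenerate <- function(iv) {
  if (iv[1L] < iv[2L]) return(iv)
  half <- max(abs(iv[1L]), 1) * 0.05
  c(iv[1L] - half, iv[2L] + half)
}

#' Select signal labels at prominent local maxima
#'
#' Candidate points are strict local maxima (higher than both neighbours;
#' for a single-point series, that point). Labels are picked greedily by
#' descending intensity, ties toward smaller x, enforcing a minimum x
#' separation of 2% of the window width so labels do not pile up on one
#' peak cluster.
#'
#' @param points Data frame with columns `x`, `y`, sorted ascending by x.
#' @param max_labels Maximum number of labels.
#' @param window x interval used for the separation rule; defaults to the
#'   point range.
#' @param precision Decimals used to format the x value as the label text.
#' @param min_sep_frac Minimum separation as a fraction of the window width.
#' @return Data frame with columns `x`, `y`, `label`, ordered by descending
#'   `y`.
#' @export
pick_signal_labels <- function(points, max_labels = 5L, window = NULL,
                               precision = 2L, min_sep_frac = 0.02) {
  n <- nrow(points)
  empty <- data.frame(x = numeric(0), y = numeric(0), label = character(0))
  if (n == 0L || max_labels < 1L) return(empty)
  x <- points$x; y <- points$y
  if (n == 1L) {
    cand <- 1L
  } else {
    left_ok <- c(TRUE, y[-1L] > y[-n])
    right_ok <- c(y[-n] > y[-1L], TRUE)
    cand <- which(left_ok & right_ok)
  }
  if (length(cand) == 0L) return(empty)
  if (is.null(window)) window <- range(x)
  min_sep <- min_sep_frac * (window[2L] - window[1L])
  cand <- cand[order(-y[cand], x[cand])]
  chosen <- integer(0)
  for (i in cand) {
    if (length(chosen) >= max_labels) break
    if (all(abs(x[i] - x[chosen]) >= min_sep)) chosen <- c(chosen, i)
  }
  data.frame(x = x[chosen], y = y[chosen],
             label = sprintf(paste0("%.", precision, "f"), x[chosen]))
}
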