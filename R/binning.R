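#' Extremum-preserving per-pixel binning of a series
#'
#' Downsamples an x-sorted point list to at most one representative point per
#' bin. The x window `[lo, hi]` is partitioned into `n_bins` equal half-open
#' intervals `[lo + i*w, lo + (i+1)*w)`, the last bin closed at `hi`. For
#' each non-empty bin the ORIGINAL point (x and y untouched, never a bin
#' centre or an interpolated value) with the extremal y is emitted:
#' the maximum for `mode = "max"` (NMR, MS, time series) or the minimum for
#' `mode = "min"` (IR transmittance, whose signal lives in absorption
#' valleys). Ties on the extremal y are broken toward the smallest x.
#' Points outside the window are dropped.
#'
#' Because every emitted point is a member of the input, binning preserves
#' exact peak positions (for signal labels and annotation anchoring), the
#' global extremum inside the window, and is idempotent: binning an
#' already-binned series with the same request is the identity.
#'
#' @param points Data frame with numeric columns `x` (sorted ascending) and
#'   `y`; extra columns are carried through.
#' @param x_window Numeric length-2 vector `c(lo, hi)` with `lo < hi`, in
#'   domain units.
#' @param n_bins Positive integer; for a chart this is
#'   `plot width in px %/% binwidth_px`.
#' @param mode `"max"` or `"min"`.
#' @return A data frame with at most `n_bins` rows, sorted ascending by x.
#' @export
#' @examples
#' pts <- data.frame(x = c(1.0, 1.4, 2.1), y = c(5, 3, 7))
#' bin_series(pts, c(1, 3), 2, "max")  # keeps (1.0, 5) and (2.1, 7)
#' bin_series(pts, c(1, 3), 2, "min")  # keeps (1.4, 3) and (2.1, 7)
bin_series <- function(points, x_window, n_bins, mode = c("max", "min")) {
  mode <- match.arg(mode)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) st_value_error("n_bins must be >= 1")
  if (length(x_window) != 2L || !all(is.finite(x_window)) || x_window[1L] >= x_window[2L])
    st_value_error("x_window must be a finite interval with lo < hi")
  if (is.unsorted(points$x)) st_contract_error("points must be sorted ascending by x")

  lo <- x_window[1L]; hi <- x_window[2L]
  keep <- points$x >= lo & points$x <= hi
  p <- points[keep, , drop = FALSE]
  if (nrow(p) == 0L) {
    rownames(p) <- NULL
    return(p)
  }
  w <- (hi - lo) / n_bins
  idx <- pmin(as.integer(floor((p$x - lo) / w)), n_bins - 1L)
  ord <- if (mode == "max") order(idx, -p$y, p$x) else order(idx, p$y, p$x)
  p <- p[ord, , drop = FALSE]
  out <- p[!duplicated(idx[ord]), , drop = FALSE]
  out <- out[order(out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin every series of a dataset for a given plot width
#'
#' Applies [bin_series()] independently to each 1D series of a dataset using
#' `n_bins = plot_width_px %/% binwidth_px`. If the dataset's bin
#' configuration is disabled, series pass through point-for-point unchanged.
#' 2D point sets (`kind = "points2d"`) are never binned.
#'
#' @param ds An `st_dataset`.
#' @param plot_width_px Plot area width in pixels (positive integer, must be
#'   at least `binwidth_px`).
#' @param mode `"max"` or `"min"`; dictated by the chart type.
#' @param x_window Optional window to bin against; defaults to the dataset's
#'   full x extent. Rendering bins against the current view window.
#' @return The dataset with binned series (extents are left untouched: they
#'   describe the full data).
#' @export
bin_dataset <- function(ds, plot_width_px, mode = c("max", "min"), x_window = NULL) {
  stopifnot(inherits(ds, "st_dataset"))
  mode <- match.arg(mode)
  if (!ds$bin$enabled) return(ds)
  plot_width_px <- as.integer(plot_width_px)
  if (is.na(plot_width_px) || plot_width_px < ds$bin$binwidth_px)
    st_value_error("plot_width_px must be at least binwidth_px")
  if (is.null(x_window)) x_window <- ds$x_extent
  if (is.null(x_window)) return(ds)
  n_bins <- plot_width_px %/% ds$bin$binwidth_px
  ds$series <- lapply(ds$series, function(s) {
    if (identical(s$kind, "points2d")) return(s)
    s$points <- bin_series(s$points, x_window, n_bins, mode)
    s
  })
  ds
}
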