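#' Domain-to-pixel scale
#'
#' A scale maps a data domain `[d0, d1]` onto a pixel range `[r0, r1]`,
#' either linearly or through a log10 transform. `reversed = TRUE` flips the
#' range endpoints, which is how the right-to-left x axes of NMR (ppm) and
#' IR (wavenumber) charts, and the downward pixel y axis of SVG, are
#' realised.
#'
#' @param kind `"linear"` or `"log10"`.
#' @param domain Numeric `c(d0, d1)` with `d0 < d1`; for log10 scales
#'   `d0 > 0`.
#' @param range_px Numeric `c(r0, r1)` with `r0 <= r1`, in pixels.
#' @param reversed Flip the direction of the mapping.
#' @return An object of class `st_scale`.
#' @export
st_scale <- function(kind = c("linear", "log10"), domain, range_px, reversed = FALSE) {
  kind <- match.arg(kind)
  if (length(domain) != 2L || !all(is.finite(domain)) || domain[1L] >= domain[2L])
    st_value_error("domain must be a finite interval with d0 < d1")
  if (kind == "log10" && domain[1L] <= 0)
    st_value_error("log10 scale requires a strictly positive domain")
  if (length(range_px) != 2L || !all(is.finite(range_px)) || range_px[1L] > range_px[2L])
    st_value_error("range_px must satisfy r0 <= r1")
  structure(list(kind = kind, domain = as.numeric(domain),
                 range_px = as.numeric(range_px), reversed = isTRUE(reversed)),
            class = "st_scale")
}

scale_transform <- function(scale, v) {
  if (scale$kind == "log10") {
    if (any(v <= 0)) st_value_error("log10 scale cannot map non-positive values")
    log10(v)
  } else v
}

#' Apply a scale: data value to pixel coordinate
#'
#' Linear: `r0 + (v - d0)/(d1 - d0) * (r1 - r0)`; log10 applies the same
#' formula to log-transformed domain and value. Values outside the domain
#' extrapolate (the renderer clips); a reversed scale maps `d0` to `r1` and
#' `d1` to `r0`.
#'
#' @param scale An `st_scale`.
#' @param v Numeric vector of data values.
#' @return Pixel coordinates (numeric vector).
#' @export
scale_apply <- function(scale, v) {
  d <- scale_transform(scale, scale$domain)
  t <- (scale_transform(scale, v) - d[1L]) / (d[2L] - d[1L])
  if (scale$reversed) t <- 1 - t
  scale$range_px[1L] + t * (scale$range_px[2L] - scale$range_px[1L])
}

#' Invert a scale: pixel coordinate back to data value
#'
#' @param scale An `st_scale`; its pixel range must be non-degenerate.
#' @param px Numeric vector of pixel coordinates.
#' @return Data values such that `scale_invert(s, scale_apply(s, v))`
#'   round-trips to `v` within 1e-9 relative tolerance.
#' @export
scale_invert <- function(scale, px) {
  r <- scale$range_px
  if (r[1L] == r[2L]) st_value_error("cannot invert a scale with a degenerate pixel range")
  t <- (px - r[1L]) / (r[2L] - r[1L])
  if (scale$reversed) t <- 1 - t
  d <- scale_transform(scale, scale$domain)
  u <- d[1L] + t * (d[2L] - d[1L])
  if (scale$kind == "log10") 10^u else u
}

# Nearest "nice" step (1/2/5 x 10^k) to span/target; rounding rather than
# ceiling keeps the resulting tick count within [target/2, 2*target].
nice_step <- function(span, target) {
  raw <- span / target
  mag <- 10^floor(log10(raw))
  frac <- raw / mag
  step <- if (frac < 1.5) 1 else if (frac < 3) 2 else if (frac < 7) 5 else 10
  step * mag
}

#' Axis tick positions and labels
#'
#' Tick values are "nice" multiples of 1, 2 or 5 times a power of ten lying
#' inside the domain; log10 scales get one tick per decade. Ticks are
#' returned in display order, i.e. reversed scales list the larger values
#' first.
#'
#' @param scale An `st_scale`.
#' @param target_count Desired approximate number of ticks.
#' @return A data frame with columns `value` and `label`.
#' @export
scale_ticks <- function(scale, target_count = 5L) {
  target_count <- max(1L, as.integer(target_count))
  d <- scale$domain
  if (scale$kind == "log10") {
    ks <- seq.int(ceiling(log10(d[1L]) - 1e-9), floor(log10(d[2L]) + 1e-9))
    vals <- 10^ks
    if (length(vals) < 2L)  # fewer than two decades: fall back to linear ticks
      vals <- linear_ticks(d, target_count)
  } else {
    vals <- linear_ticks(d, target_count)
  }
  if (scale$reversed) vals <- rev(vals)
  data.frame(value = vals, label = vapply(vals, fmt_tick, character(1L)))
}

linear_ticks <- function(d, target_count) {
  step <- nice_step(d[2L] - d[1L], target_count)
  ks <- seq.int(ceiling(d[1L] / step - 1e-9), floor(d[2L] / step + 1e-9))
  ks * step
}

# Stable decimal formatting for tick labels (no scientific notation drift).
fmt_tick <- function(v) {
  s <- sprintf("%.6f", v)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}
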