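#' Style configuration
#'
#' Visual styling of rendered charts (the renderer takes all style from this
#' object rather than an external stylesheet, so output documents are
#' standalone). Colors are assigned to series from `color_cycle` in add
#' order; a series' own `color` field wins.
#'
#' @param font_family CSS font family used for all text.
#' @param font_size Base font size in pixels.
#' @param stroke_width Series stroke width in pixels.
#' @param axis_stroke_width Axis/tick stroke width in pixels.
#' @param color_cycle Character vector of CSS colors cycled over series.
#' @param background Background fill color.
#' @param axis_color Color for axes, ticks and their labels.
#' @param dim_opacity Opacity applied to non-highlighted series when a
#'   highlight is active.
#' @param point_radius Marker radius for point-style charts, pixels.
#' @return An object of class `st_style`.
#' @export
st_style <- function(font_family = "sans-serif", font_size = 11,
                     stroke_width = 1, axis_stroke_width = 1,
                     color_cycle = c("#1f77b4", "#d62728", "#2ca02c", "#9467bd",
                                     "#ff7f0e", "#8c564b", "#17becf", "#7f7f7f"),
                     background = "#ffffff", axis_color = "#333333",
                     dim_opacity = 0.3, point_radius = 2.5) {
  structure(list(font_family = font_family, font_size = font_size,
                 stroke_width = stroke_width,
                 axis_stroke_width = axis_stroke_width,
                 color_cycle = color_cycle, background = background,
                 axis_color = axis_color, dim_opacity = dim_opacity,
                 point_radius = point_radius),
            class = "st_style")
}
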