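# SVG emission. Documents are assembled as text with fixed-precision pixel
# coordinates so that identical inputs produce byte-identical output.

px <- function(v) sprintf("%.2f", v)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub("\"", "&quot;", s, fixed = TRUE)
}

svg_tag <- function(name, attrs, close = TRUE, content = NULL) {
  a <- paste0(names(attrs), "=\"", vapply(attrs, as.character, character(1L)), "\"",
              collapse = " ")
  if (is.null(content) && close) return(paste0("<", name, " ", a, "/>"))
  open <- paste0("<", name, " ", a, ">")
  if (!close) return(open)
  paste0(open, content, "</", name, ">")
}

svg_text <- function(x, y, s, attrs = c()) {
  svg_tag("text", c(list(x = px(x), y = px(y)), attrs), content = xml_escape(s))
}

sanitize_id <- function(name) gsub("[^A-Za-z0-9_.-]", "-", name)

clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

# Approximate text width: 0.6 em per character (glyph metrics are not
# available to a renderer-independent layout).
text_width <- function(s, font_size) nchar(s) * 0.6 * font_size

#' Render a chart to SVG text
#'
#' Runs the full pipeline: resolve the view window, build the x/y scales
#' (accounting for axis reversal and the downward SVG pixel y axis), bin
#' each series against the view for the plot width, and emit a standalone
#' SVG 1.1 document containing, in fixed order: background, series geometry,
#' signal labels, legend, annotation callouts, and axes with ticks, axis
#' labels and title. Output is byte-identical across runs for identical
#' inputs.
#'
#' Series geometry depends on the chart type's render style: `impulse` draws
#' one vertical line per point from the zero baseline (mass spectra),
#' `line` draws one polyline per series, `point` one circle marker per
#' point. Every series becomes one `<g class="series">` group whose id is
#' derived from the series name.
#'
#' @param spec An `st_chart_spec` from [chart_spec()].
#' @param options An `st_chart_options` from [chart_options()].
#' @param ds An `st_dataset`; may be empty (renders frame and axes only).
#' @param annotations Optional `st_annotations` set from
#'   [parse_annotations()].
#' @param annotation_group Group to render from `annotations`; default the
#'   first group.
#' @param style An `st_style`.
#' @param resolver Function mapping a structure-url annotation value to
#'   molfile text; default reads a local file path.
#' @return SVG document text (single string, UTF-8).
#' @export
render_chart <- function(spec, options, ds, annotations = NULL,
                         annotation_group = NULL, style = st_style(),
                         resolver = read_text_resolver) {
  stopifnot(inherits(spec, "st_chart_spec"), inherits(options, "st_chart_options"),
            inherits(ds, "st_dataset"))
  m <- options$margins
  x0 <- m[["left"]]; x1 <- options$width_px - m[["right"]]
  y0 <- m[["top"]];  y1 <- options$height_px - m[["bottom"]]
  if (x1 <= x0 || y1 <= y0)
    st_layout_error("margins leave no plot area")

  view <- resolve_view(spec, options, ds)
  xscale <- st_scale("linear", view$x, c(x0, x1), reversed = spec$x_reversed)
  yscale <- st_scale("linear", view$y, c(y0, y1), reversed = !spec$y_reversed)

  plot_w <- as.integer(floor(x1 - x0))
  vis <- visible_series(ds, spec, view, plot_w)

  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    svg_tag("svg", list(xmlns = "http://www.w3.org/2000/svg", version = "1.1",
                        width = options$width_px, height = options$height_px,
                        viewBox = paste(0, 0, options$width_px, options$height_px)),
            close = FALSE),
    svg_tag("rect", list(class = "background", x = 0, y = 0,
                         width = options$width_px, height = options$height_px,
                         fill = style$background))
  )
  out <- c(out, render_series_layer(vis, spec, options, style, xscale, yscale,
                                    x0, x1, y0, y1))
  if (options$signal_labels)
    out <- c(out, render_signal_labels(vis, spec, options, style, xscale, yscale,
                                       view, y0))
  if (options$legend && length(vis))
    out <- c(out, render_legend(vis, style, x1, y0))
  if (!is.null(annotations)) {
    anchor_to <- if (!is.null(options$highlight)) options$highlight
                 else if (length(ds$series)) names(ds$series)[1L] else NULL
    if (!is.null(anchor_to)) {
      grp <- if (is.null(annotation_group)) annotations$groups[1L] else annotation_group
      anc <- anchor_annotations(annotations, grp, ds$series[[anchor_to]])
      out <- c(out, render_annotations(anc$matched, annotations$schema,
                                       xscale, yscale, view, style, resolver))
    }
  }
  out <- c(out, render_axes(spec, options, style, xscale, yscale, x0, x1, y0, y1))
  out <- c(out, "</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

# Bin (or pass through) and window-filter every 1D series; returns the list
# of series with render-ready points.
visible_series <- function(ds, spec, view, plot_w) {
  lapply(seq_along(ds$series), function(i) {
    s <- ds$series[[i]]
    s$index <- i
    p <- s$points
    if (!identical(s$kind, "points2d")) {
      if (!identical(spec$bin_mode, "none") && ds$bin$enabled &&
          plot_w >= ds$bin$binwidth_px) {
        p <- bin_series(p, view$x, plot_w %/% ds$bin$binwidth_px, spec$bin_mode)
      } else {
        p <- p[p$x >= view$x[1L] & p$x <= view$x[2L], , drop = FALSE]
      }
    } else {
      p <- p[p$x >= view$x[1L] & p$x <= view$x[2L] &
             p$y >= view$y[1L] & p$y <= view$y[2L], , drop = FALSE]
    }
    s$points <- p
    s
  })
}

series_color <- function(s, style) {
  if (!is.null(s$color)) s$color else
    style$color_cycle[((s$index - 1L) %% length(style$color_cycle)) + 1L]
}

render_series_layer <- function(vis, spec, options, style, xscale, yscale,
                                x0, x1, y0, y1) {
  out <- svg_tag("g", list(class = "series-layer"), close = FALSE)
  base_v <- clamp(0, yscale$domain[1L], yscale$domain[2L])
  base_px <- scale_apply(yscale, base_v)
  for (s in vis) {
    col <- series_color(s, style)
    dim <- !is.null(options$highlight) && !identical(options$highlight, s$name)
    gattrs <- list(class = "series", id = paste0("series--", sanitize_id(s$name)),
                   stroke = col, fill = "none",
                   `stroke-width` = style$stroke_width)
    if (dim) gattrs$opacity <- style$dim_opacity
    out <- c(out, svg_tag("g", gattrs, close = FALSE))
    p <- s$points
    if (nrow(p)) {
      cx <- clamp(scale_apply(xscale, p$x), x0, x1)
      cy <- clamp(scale_apply(yscale, p$y), y0, y1)
      if (identical(spec$render_style, "impulse")) {
        out <- c(out, vapply(seq_len(nrow(p)), function(j)
          svg_tag("line", list(x1 = px(cx[j]), y1 = px(base_px),
                               x2 = px(cx[j]), y2 = px(cy[j]))),
          character(1L)))
      } else if (identical(spec$render_style, "line")) {
        pts <- paste(px(cx), px(cy), sep = ",", collapse = " ")
        out <- c(out, svg_tag("polyline", list(points = pts)))
      } else {
        out <- c(out, vapply(seq_len(nrow(p)), function(j)
          svg_tag("circle", list(cx = px(cx[j]), cy = px(cy[j]),
                                 r = style$point_radius, fill = col,
                                 stroke = "none")),
          character(1L)))
      }
    }
    out <- c(out, "</g>")
  }
  c(out, "</g>")
}

render_signal_labels <- function(vis, spec, options, style, xscale, yscale,
                                 view, y0) {
  out <- svg_tag("g", list(class = "signal-labels", fill = style$axis_color,
                           `font-family` = style$font_family,
                           `font-size` = style$font_size,
                           `text-anchor` = "middle"), close = FALSE)
  for (s in vis) {
    if (identical(s$kind, "points2d")) next
    lab <- pick_signal_labels(s$points, max_labels = options$max_labels,
                              window = view$x, precision = spec$precision)
    if (!nrow(lab)) next
    lx <- scale_apply(xscale, lab$x)
    ly <- pmax(scale_apply(yscale, lab$y) - 4, y0 + style$font_size)
    out <- c(out, vapply(seq_len(nrow(lab)), function(j)
      svg_text(lx[j], ly[j], lab$label[j]), character(1L)))
  }
  c(out, "</g>")
}

render_legend <- function(vis, style, x1, y0) {
  fs <- style$font_size
  entry_h <- fs + 6
  names <- vapply(vis, function(s) s$name, character(1L))
  w <- 14 + 6 + max(text_width(names, fs)) + 16
  h <- entry_h * length(vis) + 10
  bx <- x1 - w - 8; by <- y0 + 8
  out <- c(
    svg_tag("g", list(class = "legend", `font-family` = style$font_family,
                      `font-size` = fs), close = FALSE),
    svg_tag("rect", list(x = px(bx), y = px(by), width = px(w), height = px(h),
                         fill = "#ffffff", stroke = style$axis_color,
                         `fill-opacity` = "0.8"))
  )
  for (i in seq_along(vis)) {
    ey <- by + 5 + (i - 1) * entry_h + entry_h / 2
    out <- c(out,
      svg_tag("g", list(class = "legend-entry"), close = FALSE),
      svg_tag("line", list(x1 = px(bx + 8), y1 = px(ey), x2 = px(bx + 22),
                           y2 = px(ey), stroke = series_color(vis[[i]], style),
                           `stroke-width` = 2)),
      svg_text(bx + 28, ey + fs * 0.35, names[i],
               c(fill = style$axis_color)),
      "</g>")
  }
  c(out, "</g>")
}

render_axes <- function(spec, options, style, xscale, yscale, x0, x1, y0, y1) {
  fs <- style$font_size
  out <- svg_tag("g", list(class = "axes", stroke = style$axis_color,
                           `stroke-width` = style$axis_stroke_width,
                           `font-family` = style$font_family,
                           `font-size` = fs, fill = "none"), close = FALSE)
  out <- c(out,
    svg_tag("line", list(x1 = px(x0), y1 = px(y1), x2 = px(x1), y2 = px(y1))),
    svg_tag("line", list(x1 = px(x0), y1 = px(y0), x2 = px(x0), y2 = px(y1))))
  xt <- scale_ticks(xscale, max(2L, as.integer((x1 - x0) / 100)))
  for (j in seq_len(nrow(xt))) {
    tx <- scale_apply(xscale, xt$value[j])
    out <- c(out,
      svg_tag("line", list(x1 = px(tx), y1 = px(y1), x2 = px(tx), y2 = px(y1 + 5))),
      svg_text(tx, y1 + 5 + fs, xt$label[j],
               c(fill = style$axis_color, stroke = "none",
                 `text-anchor` = "middle")))
  }
  yt <- scale_ticks(yscale, max(2L, as.integer((y1 - y0) / 60)))
  for (j in seq_len(nrow(yt))) {
    ty <- scale_apply(yscale, yt$value[j])
    out <- c(out,
      svg_tag("line", list(x1 = px(x0 - 5), y1 = px(ty), x2 = px(x0), y2 = px(ty))),
      svg_text(x0 - 8, ty + fs * 0.35, yt$label[j],
               c(fill = style$axis_color, stroke = "none",
                 `text-anchor` = "end")))
  }
  xlab <- if (!is.null(options$x_label)) options$x_label else spec$x_label_default
  ylab <- if (!is.null(options$y_label)) options$y_label else spec$y_label_default
  cx <- (x0 + x1) / 2; cy <- (y0 + y1) / 2
  if (nzchar(xlab))
    out <- c(out, svg_text(cx, options$height_px - 8, xlab,
                           c(fill = style$axis_color, stroke = "none",
                             `text-anchor` = "middle")))
  if (nzchar(ylab))
    out <- c(out, svg_tag("text",
      list(x = px(14), y = px(cy), fill = style$axis_color, stroke = "none",
           `text-anchor` = "middle",
           transform = paste0("rotate(-90 ", px(14), " ", px(cy), ")")),
      content = xml_escape(ylab)))
  if (nzchar(options$title))
    out <- c(out, svg_tag("text",
      list(x = px(cx), y = px(max(y0 - 12, fs + 4)), fill = style$axis_color,
           stroke = "none", `text-anchor` = "middle",
           `font-size` = fs + 3, `font-weight` = "bold"),
      content = xml_escape(options$title)))
  c(out, "</g>")
}

#' Render anchored annotations as an SVG fragment
#'
#' Draws, for each anchored annotation whose anchor lies inside the view
#' window (anchors outside are skipped): a marker at the anchor point, any
#' `text`-kind payload column beside it, and — when the annotation carries
#' `tooltip` or `structure_url` columns — a callout box listing one
#' `"<key>: <value>"` line per tooltip pair and embedding the 2D depiction
#' of each resolved structure.
#'
#' @param anchored The `matched` element returned by [anchor_annotations()].
#' @param schema The `st_annotation_schema` the annotations were parsed
#'   with.
#' @param xscale,yscale `st_scale` objects for the plot.
#' @param view View window list (`x`, `y`) as from [resolve_view()].
#' @param style An `st_style`.
#' @param resolver Function mapping structure-url values to molfile text.
#' @return Character vector of SVG fragment lines (a `<g class="annotations">`
#'   group).
#' @export
render_annotations <- function(anchored, schema, xscale, yscale, view,
                               style = st_style(),
                               resolver = read_text_resolver) {
  fs <- style$font_size
  out <- svg_tag("g", list(class = "annotations", `font-family` = style$font_family,
                           `font-size` = fs), close = FALSE)
  x0 <- min(xscale$range_px); x1 <- max(xscale$range_px)
  y0 <- min(yscale$range_px); y1 <- max(yscale$range_px)
  n_skipped <- 0L
  for (entry in anchored) {
    a <- entry$annotation; pt <- entry$point
    if (pt$x < view$x[1L] || pt$x > view$x[2L]) {
      n_skipped <- n_skipped + 1L
      next
    }
    ax <- scale_apply(xscale, pt$x)
    ay <- clamp(scale_apply(yscale, pt$y), y0, y1)
    out <- c(out, svg_tag("g", list(class = "annotation"), close = FALSE),
             svg_tag("circle", list(cx = px(ax), cy = px(ay), r = 3,
                                    fill = "none", stroke = style$axis_color)))
    kinds <- schema$columns$kind
    for (k in which(kinds == "text")) {
      out <- c(out, svg_text(ax + 6, ay - 6, as.character(a$payload[[k]]),
                             c(fill = style$axis_color)))
    }
    tip <- build_tooltip(a, schema, resolver = resolver)
    if (length(tip$lines) || length(tip$structures)) {
      out <- c(out, render_callout(tip, ax, ay, x0, x1, y0, y1, style))
    }
    out <- c(out, "</g>")
  }
  if (n_skipped > 0L)
    message(sprintf("skipped %d annotation(s) with anchors outside the view window",
                    n_skipped))
  c(out, "</g>")
}

render_callout <- function(tip, ax, ay, x0, x1, y0, y1, style) {
  fs <- style$font_size
  pad <- 6
  line_h <- fs + 4
  mol_size <- 80
  w <- max(c(60, text_width(tip$lines, fs) + 2 * pad,
             if (length(tip$structures)) mol_size + 2 * pad))
  h <- pad + line_h * length(tip$lines) +
       (mol_size + pad) * length(tip$structures) + pad
  bx <- ax + 10
  if (bx + w > x1) bx <- ax - 10 - w
  bx <- clamp(bx, x0, max(x0, x1 - w))
  by <- clamp(ay - 10, y0, max(y0, y1 - h))
  out <- c(
    svg_tag("g", list(class = "callout"), close = FALSE),
    svg_tag("rect", list(x = px(bx), y = px(by), width = px(w), height = px(h),
                         fill = "#fffdf0", stroke = style$axis_color,
                         `stroke-width` = 1))
  )
  cy <- by + pad
  for (s in tip$lines) {
    cy <- cy + line_h
    out <- c(out, svg_text(bx + pad, cy - 4, s, c(fill = style$axis_color)))
  }
  for (frag in tip$structures) {
    out <- c(out,
      svg_tag("g", list(transform = sprintf("translate(%s %s)",
                                            px(bx + pad), px(cy))),
              close = FALSE),
      frag, "</g>")
    cy <- cy + mol_size + pad
  }
  c(out, "</g>")
}
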