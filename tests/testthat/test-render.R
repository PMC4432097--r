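ms_dataset <- function(n = 3, seed = 5) {
  add_series(new_dataset(), sim_ms_peaks(n, seed = seed))
}

test_that("an empty dataset renders a valid frame with axes and no series", {
  svg <- render_chart(chart_spec("ms"), chart_options(), new_dataset())
  doc <- xml2::read_xml(svg)
  expect_equal(xml2::xml_name(doc), "svg")
  expect_equal(length(series_groups(doc)), 0L)
  expect_equal(length(svg_find(doc, "//*[local-name()='g'][@class='axes']")), 1L)
})

test_that("output is well-formed SVG with matching size attributes", {
  svg <- render_chart(chart_spec("ms"), chart_options(width_px = 640, height_px = 320),
                      ms_dataset())
  doc <- xml2::read_xml(svg)
  expect_equal(xml2::xml_attr(doc, "width"), "640")
  expect_equal(xml2::xml_attr(doc, "height"), "320")
  expect_equal(xml2::xml_attr(doc, "viewBox"), "0 0 640 320")
})

test_that("impulse count equals the visible peak count", {
  ds <- ms_dataset(3)
  doc <- xml2::read_xml(render_chart(chart_spec("ms"), chart_options(), ds))
  g <- series_groups(doc)
  expect_equal(length(g), 1L)
  expect_equal(length(xml2::xml_find_all(g[[1]], ".//*[local-name()='line']")), 3L)
})

test_that("each series maps to one identifiable group; legend follows add order", {
  ds <- new_dataset()
  for (k in 1:3) ds <- add_series(ds, sim_nmr_trace(500, seed = k))
  svg <- render_chart(chart_spec("nmr1d"), chart_options(legend = TRUE), ds)
  doc <- xml2::read_xml(svg)
  g <- series_groups(doc)
  expect_equal(length(g), 3L)
  expect_equal(xml2::xml_attr(g, "id"),
               paste0("series--series-", 1:3))
  entries <- svg_find(doc, "//*[local-name()='g'][@class='legend-entry']")
  expect_equal(length(entries), 3L)
  expect_equal(xml2::xml_text(xml2::xml_find_first(entries, ".//*[local-name()='text']")),
               paste0("series-", 1:3))
})

test_that("rendering is deterministic: identical inputs, identical bytes", {
  ds <- ms_dataset(12, seed = 9)
  opts <- chart_options(title = "t", legend = TRUE, signal_labels = TRUE)
  a <- render_chart(chart_spec("ms"), opts, ds)
  b <- render_chart(chart_spec("ms"), opts, ds)
  expect_identical(a, b)
})

test_that("series geometry stays inside the plot rectangle", {
  ds <- add_series(new_dataset(), sim_nmr_trace(2000, seed = 4))
  opt <- chart_options(width_px = 400, height_px = 300,
                       view_window = list(x = c(2, 8)))
  svg <- render_chart(chart_spec("nmr1d"), opt, ds)
  doc <- xml2::read_xml(svg)
  poly <- svg_find(doc, "//*[local-name()='g'][@class='series']/*[local-name()='polyline']")
  expect_equal(length(poly), 1L)
  coords <- as.numeric(unlist(strsplit(xml2::xml_attr(poly, "points"), "[ ,]")))
  xs <- coords[c(TRUE, FALSE)]; ys <- coords[c(FALSE, TRUE)]
  m <- chart_options()$margins
  expect_true(all(xs >= m[["left"]] - 1e-9 & xs <= 400 - m[["right"]] + 1e-9))
  expect_true(all(ys >= m[["top"]] - 1e-9 & ys <= 300 - m[["bottom"]] + 1e-9))
})

test_that("point-style 2D charts draw one marker per visible cross peak", {
  ds <- add_series(new_dataset(), sim_nmr2d_points(25, seed = 2))
  doc <- xml2::read_xml(render_chart(chart_spec("nmr2d"), chart_options(), ds))
  pts <- svg_find(doc, "//*[local-name()='g'][@class='series']/*[local-name()='circle']")
  expect_equal(length(pts), 25L)
})

test_that("highlight dims every other series", {
  ds <- new_dataset()
  for (k in 1:2) ds <- add_series(ds, sim_ms_peaks(5, seed = k))
  svg <- render_chart(chart_spec("ms"), chart_options(highlight = "series-2"), ds)
  doc <- xml2::read_xml(svg)
  g <- series_groups(doc)
  expect_equal(xml2::xml_attr(g, "opacity"), c("0.3", NA))
})

test_that("title, axis labels and signal labels appear as text", {
  ds <- ms_dataset(6, seed = 13)
  svg <- render_chart(chart_spec("ms"),
                      chart_options(title = "My spectrum", signal_labels = TRUE),
                      ds)
  expect_match(svg, ">My spectrum</text>", fixed = TRUE)
  expect_match(svg, ">m/z</text>", fixed = TRUE)
  labs <- svg_find(xml2::read_xml(svg),
                   "//*[local-name()='g'][@class='signal-labels']/*[local-name()='text']")
  expect_gt(length(labs), 0L)
  expect_true(all(grepl("^[0-9]+\\.[0-9]{2}$", xml2::xml_text(labs))))
})

test_that("degenerate margins raise a layout error", {
  expect_error(render_chart(chart_spec("ms"),
                            chart_options(width_px = 50, height_px = 50),
                            ms_dataset()),
               class = "st_layout_error")
})

test_that("text content is XML-escaped", {
  ds <- add_series(new_dataset(),
                   new_series("a<b&c", data.frame(x = 1:2, y = 1:2)))
  svg <- render_chart(chart_spec("timeseries"),
                      chart_options(title = "x < y & z", legend = TRUE), ds)
  expect_no_error(xml2::read_xml(svg))
  expect_match(svg, "x &lt; y &amp; z", fixed = TRUE)
})
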