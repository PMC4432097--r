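frag_schema <- function() {
  annotation_schema(c("fragment", "mz"), c("tooltip", "tooltip"))
}

test_that("rows partition into groups preserving file order", {
  js <- '[["frag", 113.0, "uracil", "113.00"],
          ["frag", 245.1, "ribose loss", "245.08"],
          ["ref", 267.1, "parent ion", "267.07"]]'
  set <- parse_annotations(js, frag_schema())
  expect_equal(set$groups, c("frag", "ref"))
  expect_equal(length(set$annotations), 3L)
  # partition: group counts sum to the row count
  grp <- vapply(set$annotations, `[[`, character(1), "group")
  expect_equal(sum(table(grp)), 3L)
  expect_equal(set$annotations[[1]]$x_lookup, 113.0)
  expect_equal(set$annotations[[1]]$payload$fragment, "uracil")
})

test_that("schema violations name the offending row", {
  js <- '[["frag", 113.0, "uracil"]]'
  err <- tryCatch(parse_annotations(js, frag_schema()), error = identity)
  expect_s3_class(err, "st_schema_error")
  expect_match(conditionMessage(err), "row 1")
  expect_error(parse_annotations('[["frag", "abc", "u", "1"]]', frag_schema()),
               class = "st_value_error")
  expect_error(parse_annotations('[["a", 1, ""]]',
                                 annotation_schema("s", "structure_url")),
               class = "st_value_error")
  expect_error(annotation_schema(c("a", "a"), c("text", "text")),
               class = "st_value_error")
  expect_error(annotation_schema("a", "sound"), class = "st_value_error")
})

test_that("parse -> serialize -> parse is the identity on annotation sets", {
  js <- '[["a",1.5,"p"],["b",2.5,"q"],["a",3.5,"r"]]'
  schema <- annotation_schema("note", "tooltip")
  set <- parse_annotations(js, schema)
  rows <- lapply(set$annotations, function(a)
    c(list(a$group, a$x_lookup), unname(a$payload)))
  back <- parse_annotations(jsonlite::toJSON(rows, auto_unbox = TRUE), schema)
  expect_equal(back$annotations, set$annotations)
  expect_equal(back$groups, set$groups)
})

test_that("anchoring matches a brute-force nearest-x scan with tie to smaller x", {
  set.seed(31)
  s <- new_series("s", random_series_points(200))
  xs <- s$points$x
  set <- parse_annotations(
    jsonlite::toJSON(lapply(runif(25, -5, 105),
                            function(v) list("g", v)), auto_unbox = TRUE),
    annotation_schema())
  res <- anchor_annotations(set, "g", s, rel_tolerance = 0.05)
  width <- diff(range(xs))
  for (m in res$matched) {
    j <- oracle_nearest(xs, m$annotation$x_lookup)
    expect_equal(m$point$x, xs[j])
    expect_lte(m$distance, 0.05 * width)
  }
  for (u in res$unmatched) {
    j <- oracle_nearest(xs, u$x_lookup)
    expect_gt(abs(xs[j] - u$x_lookup), 0.05 * width)
  }
  expect_equal(length(res$matched) + length(res$unmatched), 25L)
  # exact hit binds at distance zero
  hit <- parse_annotations(sprintf('[["g", %.10f]]', xs[7]), annotation_schema())
  got <- anchor_annotations(hit, "g", s)
  expect_equal(got$matched[[1]]$distance, 0)
  # ties between equidistant points break toward smaller x
  ts <- new_series("t", data.frame(x = c(1, 3), y = c(5, 6)))
  tie <- parse_annotations('[["g", 2.0]]', annotation_schema())
  expect_equal(anchor_annotations(tie, "g", ts, rel_tolerance = 1)$matched[[1]]$point$x, 1)
  expect_error(anchor_annotations(set, "missing", s), class = "st_notfound_error")
})

test_that("far-outside lookups are reported unmatched, not fatal", {
  s <- new_series("s", data.frame(x = c(1, 2), y = c(1, 1)))
  set <- parse_annotations('[["g", 500.0]]', annotation_schema())
  res <- anchor_annotations(set, "g", s)
  expect_equal(length(res$matched), 0L)
  expect_equal(length(res$unmatched), 1L)
})

test_that("tooltip lines follow the '<key>: <value>' format exactly", {
  set <- parse_annotations('[["frag", 113.0, "uracil", "113.00"]]', frag_schema())
  tip <- build_tooltip(set$annotations[[1]], frag_schema())
  expect_equal(tip$lines, c("fragment: uracil", "mz: 113.00"))
})

test_that("structure columns resolve, embed a depiction, and degrade gracefully", {
  dir <- withr::local_tempdir()
  writeLines(fixture_molfile("uracil"), file.path(dir, "uracil.mol"))
  schema <- annotation_schema(c("fragment", "structure"),
                              c("tooltip", "structure_url"))
  set <- parse_annotations(
    sprintf('[["frag", 113.0, "uracil", "%s"]]',
            file.path(dir, "uracil.mol")),
    schema)
  tip <- build_tooltip(set$annotations[[1]], schema)
  expect_equal(length(tip$structures), 1L)
  expect_equal(nrow(tip$molecules[[1]]$atoms), 8L)
  expect_match(tip$structures[[1]], "class=\"molecule\"", fixed = TRUE)
  # resolver miss: placeholder line, other columns intact
  miss <- parse_annotations('[["frag", 113.0, "uracil", "no-such-file.mol"]]',
                            schema)
  tip2 <- build_tooltip(miss$annotations[[1]], schema)
  expect_equal(length(tip2$structures), 0L)
  expect_equal(tip2$lines[1], "fragment: uracil")
  expect_match(tip2$lines[2], "^structure: <error: ")
})

test_that("annotations render into the chart and clip to the view window", {
  dir <- withr::local_tempdir()
  writeLines(fixture_molfile("benzene"), file.path(dir, "benzene.mol"))
  s <- new_series("s", data.frame(x = c(100, 113, 250), y = c(10, 80, 40)))
  ds <- add_series(new_dataset(), s)
  schema <- annotation_schema(c("fragment", "structure"),
                              c("tooltip", "structure_url"))
  set <- parse_annotations(
    sprintf('[["frag", 113.0, "benzene", "%s"], ["frag", 250.0, "other", "%s"]]',
            file.path(dir, "benzene.mol"), file.path(dir, "benzene.mol")),
    schema)
  svg <- render_chart(chart_spec("ms"), chart_options(), ds, annotations = set)
  doc <- xml2::read_xml(svg)
  expect_equal(length(svg_find(doc, "//*[local-name()='g'][@class='annotation']")), 2L)
  expect_gt(length(svg_find(doc, "//*[local-name()='g'][@class='molecule']")), 0L)
  expect_match(svg, ">fragment: benzene</text>", fixed = TRUE)
  # anchors outside the view window are skipped
  opt <- chart_options(view_window = list(x = c(90, 150), y = c(0, 100)))
  expect_message(
    svg2 <- render_chart(chart_spec("ms"), opt, ds, annotations = set),
    "skipped 1")
  doc2 <- xml2::read_xml(svg2)
  expect_equal(length(svg_find(doc2, "//*[local-name()='g'][@class='annotation']")), 1L)
})
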