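test_that("the fixture corpus parses with atom/bond counts per counts line", {
  b <- parse_molfile(fixture_molfile("benzene"))
  expect_equal(nrow(b$atoms), 6L)
  expect_equal(nrow(b$bonds), 6L)
  expect_true(all(b$atoms$element == "C"))
  m <- parse_molfile(fixture_molfile("methane"))
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(nrow(m$bonds), 0L)
  e <- parse_molfile(fixture_molfile("ethanol"))
  expect_equal(e$atoms$element, c("C", "C", "O"))
  expect_equal(e$bonds, data.frame(a1 = c(1L, 2L), a2 = c(2L, 3L),
                                   order = c(1L, 1L)))
  u <- parse_molfile(fixture_molfile("uracil"))
  expect_equal(sum(u$atoms$element == "N"), 2L)
  expect_equal(sum(u$atoms$element == "O"), 2L)
  expect_equal(nrow(u$bonds), 8L)
})

test_that("corrupted variants raise their documented errors", {
  expect_error(parse_molfile(fixture_molfile("corrupt_truncated")),
               class = "st_parse_error")
  expect_error(parse_molfile(fixture_molfile("corrupt_counts")),
               class = "st_parse_error")
  expect_error(parse_molfile(fixture_molfile("corrupt_v3000")),
               class = "st_dialect_error")
  # bond index out of range
  bad <- write_molfile("bad",
                       data.frame(element = c("C", "C"), x = c(0, 1), y = c(0, 0)),
                       data.frame(a1 = 1L, a2 = 5L, order = 1L))
  expect_error(parse_molfile(bad), class = "st_parse_error")
})

test_that("M CHG property lines set atomic charges", {
  txt <- write_molfile("ion",
                       data.frame(element = c("N", "O"), x = c(0, 1), y = c(0, 0),
                                  charge = c(1L, -1L)),
                       data.frame(a1 = 1L, a2 = 2L, order = 1L))
  mol <- parse_molfile(txt)
  expect_equal(mol$atoms$charge, c(1L, -1L))
})

test_that("parser agrees with an independent cheminformatics reader", {
  skip_if_not_installed("ChemmineR")
  for (nm in c("ethanol", "benzene", "uracil")) {
    path <- tempfile(fileext = ".mol")
    writeLines(fixture_molfile(nm), path)
    ours <- parse_molfile(fixture_molfile(nm))
    ref <- ChemmineR::read.SDFset(path)[[1]]
    ab <- ChemmineR::atomblock(ref)
    bb <- ChemmineR::bondblock(ref)
    expect_equal(nrow(ours$atoms), nrow(ab))
    expect_equal(nrow(ours$bonds), nrow(bb))
    expect_equal(ours$atoms$element, gsub("_.*$", "", rownames(ab)))
    expect_equal(ours$bonds$a1, unname(bb[, 1]))
    expect_equal(ours$bonds$a2, unname(bb[, 2]))
    expect_equal(ours$bonds$order, unname(bb[, 3]))
  }
})

depict_lines <- function(frag) {
  doc <- xml2::read_xml(frag)
  length(xml2::xml_find_all(doc, ".//*[local-name()='line']"))
}
depict_labels <- function(frag) {
  doc <- xml2::read_xml(frag)
  length(xml2::xml_find_all(doc, ".//*[local-name()='text']"))
}

test_that("depiction line count is the sum of bond orders, labels heteroatoms", {
  # two carbons, one single bond: 1 line, no label
  cc <- parse_molfile(write_molfile("cc",
          data.frame(element = c("C", "C"), x = c(0, 1), y = c(0, 0)),
          data.frame(a1 = 1L, a2 = 2L, order = 1L)))
  expect_equal(depict_lines(depict(cc)), 1L)
  expect_equal(depict_labels(depict(cc)), 0L)
  # benzene: 3 single + 3 double = 9 lines, no labels
  bz <- parse_molfile(fixture_molfile("benzene"))
  expect_equal(depict_lines(depict(bz)), 9L)
  expect_equal(depict_labels(depict(bz)), 0L)
  # C-O: 1 line and an "O" label
  co <- parse_molfile(write_molfile("co",
          data.frame(element = c("C", "O"), x = c(0, 1), y = c(0, 0)),
          data.frame(a1 = 1L, a2 = 2L, order = 1L)))
  frag <- depict(co)
  expect_equal(depict_lines(frag), 1L)
  expect_equal(depict_labels(frag), 1L)
  expect_match(frag, ">O</text>", fixed = TRUE)
  # uracil-like ring: sum of orders, one label per heteroatom
  u <- parse_molfile(fixture_molfile("uracil"))
  expect_equal(depict_lines(depict(u)), sum(u$bonds$order))
  expect_equal(depict_labels(depict(u)),
               sum(u$atoms$element != "C" | u$atoms$charge != 0))
})

test_that("bond ends are trimmed at labelled atoms", {
  co <- parse_molfile(write_molfile("co",
          data.frame(element = c("C", "O"), x = c(0, 1), y = c(0, 0)),
          data.frame(a1 = 1L, a2 = 2L, order = 1L)))
  doc <- xml2::read_xml(depict(co, size_px = 100))
  ln <- xml2::xml_find_first(doc, ".//*[local-name()='line']")
  lab <- xml2::xml_find_first(doc, ".//*[local-name()='text']")
  # the bond stops short of the O label centre
  expect_lt(as.numeric(xml2::xml_attr(ln, "x2")),
            as.numeric(xml2::xml_attr(lab, "x")))
})

test_that("depiction is invariant under translation and uniform scaling", {
  base <- parse_molfile(fixture_molfile("uracil"))
  shifted <- base; shifted$atoms$x <- shifted$atoms$x + 17
  shifted$atoms$y <- shifted$atoms$y - 3
  scaled <- base; scaled$atoms$x <- scaled$atoms$x * 4
  scaled$atoms$y <- scaled$atoms$y * 4
  expect_identical(depict(base), depict(shifted))
  expect_identical(depict(base), depict(scaled))
})

test_that("degenerate geometry is rejected, single atoms are not", {
  flat <- parse_molfile(write_molfile("flat",
            data.frame(element = c("C", "C"), x = c(0, 0), y = c(0, 0)),
            data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))))
  expect_error(depict(flat), class = "st_geometry_error")
  single <- parse_molfile(fixture_molfile("methane"))
  expect_no_error(depict(single))
})

test_that("aromatic bond type 4 renders as solid plus dashed inner line", {
  ar <- parse_molfile(write_molfile("ar",
          data.frame(element = c("C", "C"), x = c(0, 1), y = c(0, 0)),
          data.frame(a1 = 1L, a2 = 2L, order = 4L)))
  frag <- depict(ar)
  expect_equal(depict_lines(frag), 2L)
  expect_match(frag, "stroke-dasharray", fixed = TRUE)
})
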