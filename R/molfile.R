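#' Parse an MDL Molfile (V2000)
#'
#' Fixed-column parser for the V2000 connection-table dialect: three header
#' lines, a counts line (atom count in columns 1-3, bond count in columns
#' 4-6), an atom block (`x y z element`), a bond block (`a1 a2 order`) and a
#' terminating `M  END` line. Atomic charges are taken from `M  CHG`
#' property lines when present (a charge of 0 otherwise); the z coordinate
#' is parsed but ignored, since depiction is two-dimensional. V3000 files
#' are rejected with a dialect error rather than misparsed.
#'
#' @param text Molfile text: a single string, a character vector of lines,
#'   or a path to a `.mol` file.
#' @return An object of class `st_molecule`: a list with `title`, `atoms`
#'   (data frame: `element`, `x`, `y`, `charge`) and `bonds` (data frame:
#'   `a1`, `a2`, `order`, 1-based atom indices).
#' @export
parse_molfile <- function(text) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text, warn = FALSE)
  else if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]]
  else text
  lines <- sub("\r$", "", lines)
  if (length(lines) < 4L) st_parse_error("molfile truncated: missing counts line")

  counts <- lines[4L]
  if (grepl("V3000", counts, fixed = TRUE))
    st_dialect_error("V3000 molfiles are not supported (V2000 only)")
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(n_atoms) || is.na(n_bonds) || n_atoms < 0L || n_bonds < 0L)
    st_parse_error("malformed counts line")

  end_idx <- which(grepl("^M  END", lines))
  if (length(end_idx) == 0L)
    st_parse_error("molfile truncated: no 'M  END' terminator")
  end_idx <- end_idx[1L]

  body <- if (end_idx > 5L) lines[5L:(end_idx - 1L)] else character(0)
  prop_lines <- body[startsWith(body, "M  ")]
  ctab <- body[!startsWith(body, "M  ")]
  if (length(ctab) != n_atoms + n_bonds)
    st_parse_error(sprintf(
      "counts line mismatch: expected %d atom + %d bond lines, found %d",
      n_atoms, n_bonds, length(ctab)))

  atoms <- data.frame(element = character(n_atoms), x = numeric(n_atoms),
                      y = numeric(n_atoms), charge = integer(n_atoms),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_atoms)) {
    ln <- ctab[i]
    x <- suppressWarnings(as.numeric(substr(ln, 1L, 10L)))
    y <- suppressWarnings(as.numeric(substr(ln, 11L, 20L)))
    el <- trimws(substr(ln, 32L, 34L))
    if (is.na(x) || is.na(y))
      st_parse_error(sprintf("malformed atom line %d", i))
    if (!nzchar(el))
      st_parse_error(sprintf("missing element symbol on atom line %d", i))
    atoms$element[i] <- el; atoms$x[i] <- x; atoms$y[i] <- y
  }

  bonds <- data.frame(a1 = integer(n_bonds), a2 = integer(n_bonds),
                      order = integer(n_bonds))
  for (i in seq_len(n_bonds)) {
    ln <- ctab[n_atoms + i]
    a1 <- suppressWarnings(as.integer(substr(ln, 1L, 3L)))
    a2 <- suppressWarnings(as.integer(substr(ln, 4L, 6L)))
    o  <- suppressWarnings(as.integer(substr(ln, 7L, 9L)))
    if (is.na(a1) || is.na(a2) || is.na(o))
      st_parse_error(sprintf("malformed bond line %d", i))
    if (a1 < 1L || a1 > n_atoms || a2 < 1L || a2 > n_atoms)
      st_parse_error(sprintf("bond line %d: atom index out of range", i))
    if (a1 == a2)
      st_parse_error(sprintf("bond line %d: bond joins an atom to itself", i))
    bonds$a1[i] <- a1; bonds$a2[i] <- a2; bonds$order[i] <- o
  }

  for (pl in prop_lines[startsWith(prop_lines, "M  CHG")]) {
    toks <- scan(text = substring(pl, 7L), what = integer(), quiet = TRUE)
    npairs <- toks[1L]
    for (k in seq_len(npairs)) {
      idx <- toks[2L * k]; val <- toks[2L * k + 1L]
      if (is.na(idx) || idx < 1L || idx > n_atoms)
        st_parse_error("M  CHG references an atom index out of range")
      atoms$charge[idx] <- val
    }
  }

  structure(list(title = trimws(lines[1L]), atoms = atoms, bonds = bonds),
            class = "st_molecule")
}

#' @export
print.st_molecule <- function(x, ...) {
  cat(sprintf("<st_molecule> %s: %d atoms, %d bonds\n",
              if (nzchar(x$title)) x$title else "<untitled>",
              nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Depict a molecule as an SVG fragment
#'
#' Draws a minimal skeletal 2D depiction: the molfile coordinates are
#' translated and uniformly scaled (aspect ratio preserved) to fit a
#' `size_px` square with 10% padding, so the fragment is invariant under
#' translation or uniform scaling of the input coordinates. Single bonds
#' are one line, double bonds two parallel lines, triple bonds three;
#' the "aromatic" bond type (order 4) is drawn as a solid line with an inner
#' dashed parallel (no kekulization is attempted). Heteroatoms (any element
#' other than carbon) and charged atoms get a centred text label — with
#' adjoining bond ends trimmed back by a label radius — while carbons are
#' plain vertices. Implicit hydrogens are not drawn.
#'
#' Molfiles without meaningful 2D coordinates (all atoms at one point) raise
#' a degenerate-geometry error; coordinate generation is out of scope.
#'
#' @param mol An `st_molecule` from [parse_molfile()].
#' @param size_px Side of the square target area, pixels.
#' @param style An `st_style` (font and stroke settings).
#' @return A single string: an SVG `<g class="molecule">` fragment.
#' @export
depict <- function(mol, size_px = 120L, style = st_style()) {
  stopifnot(inherits(mol, "st_molecule"))
  size_px <- as.numeric(size_px)
  if (!is.finite(size_px) || size_px <= 0) st_value_error("size_px must be positive")
  at <- mol$atoms
  if (nrow(at) == 0L) st_geometry_error("molecule has no atoms")
  xr <- range(at$x); yr <- range(at$y)
  span <- max(xr[2L] - xr[1L], yr[2L] - yr[1L])
  if (span == 0 && nrow(at) > 1L)
    st_geometry_error("degenerate geometry: all atom coordinates identical")
  if (span == 0) span <- 1  # single atom: centred label
  s <- (0.8 * size_px) / span
  cxm <- mean(xr); cym <- mean(yr)
  # molfile y grows upward, SVG y downward
  pxa <- size_px / 2 + (at$x - cxm) * s
  pya <- size_px / 2 - (at$y - cym) * s

  labelled <- at$element != "C" | at$charge != 0L
  label_r <- 0.55 * style$font_size

  out <- svg_tag("g", list(class = "molecule", stroke = style$axis_color,
                           `stroke-width` = style$stroke_width, fill = "none",
                           `font-family` = style$font_family,
                           `font-size` = style$font_size), close = FALSE)
  for (i in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[i, ]
    p1 <- c(pxa[b$a1], pya[b$a1]); p2 <- c(pxa[b$a2], pya[b$a2])
    d <- p2 - p1
    len <- sqrt(sum(d^2))
    if (len == 0) next
    u <- d / len
    if (labelled[b$a1]) p1 <- p1 + u * label_r
    if (labelled[b$a2]) p2 <- p2 - u * label_r
    perp <- c(-u[2L], u[1L])
    off <- 2.2
    seg <- function(q1, q2, dashed = FALSE) {
      attrs <- list(x1 = px(q1[1L]), y1 = px(q1[2L]),
                    x2 = px(q2[1L]), y2 = px(q2[2L]))
      if (dashed) attrs$`stroke-dasharray` <- "3 2"
      svg_tag("line", attrs)
    }
    out <- c(out, switch(as.character(b$order),
      "2" = c(seg(p1 + perp * off / 2, p2 + perp * off / 2),
              seg(p1 - perp * off / 2, p2 - perp * off / 2)),
      "3" = c(seg(p1, p2),
              seg(p1 + perp * off, p2 + perp * off),
              seg(p1 - perp * off, p2 - perp * off)),
      "4" = c(seg(p1, p2),
              seg(p1 + perp * off, p2 + perp * off, dashed = TRUE)),
      seg(p1, p2)))
  }
  for (i in which(labelled)) {
    lab <- at$element[i]
    if (at$charge[i] > 0L)
      lab <- paste0(lab, if (at$charge[i] > 1L) at$charge[i] else "", "+")
    if (at$charge[i] < 0L)
      lab <- paste0(lab, if (at$charge[i] < -1L) -at$charge[i] else "", "-")
    out <- c(out, svg_tag("text",
      list(x = px(pxa[i]), y = px(pya[i] + 0.35 * style$font_size),
           `text-anchor` = "middle", fill = style$axis_color, stroke = "none"),
      content = xml_escape(lab)))
  }
  paste(c(out, "</g>"), collapse = "\n")
}

#' Default structure-url resolver: read a local file
#'
#' Structure annotation values are treated as references to molfile
#' documents. The default resolver interprets them as local filesystem
#' paths; supply a custom resolver to [render_chart()] or [build_tooltip()]
#' for any other lookup scheme.
#'
#' @param ref The structure-url value.
#' @return Molfile text.
#' @export
read_text_resolver <- function(ref) {
  if (!file.exists(ref)) st_notfound_error(sprintf("cannot resolve '%s'", ref))
  paste(readLines(ref, warn = FALSE), collapse = "\n")
}
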