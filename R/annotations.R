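#' Annotation schema
#'
#' Describes the payload columns of an annotation table — the columns AFTER
#' the two mandatory leading ones (group and x-domain lookup value). Each
#' payload column is typed:
#'
#' * `text` — drawn on the chart beside the anchored data point;
#' * `tooltip` — shown as a `"<key>: <value>"` line in the callout box;
#' * `structure_url` — a reference to an MDL Molfile, resolved and drawn as
#'   a 2D molecule depiction inside the callout.
#'
#' @param names Character vector of payload column names (unique; may be
#'   empty).
#' @param kinds Character vector of the same length with values `"text"`,
#'   `"tooltip"` or `"structure_url"`.
#' @return An object of class `st_annotation_schema`.
#' @export
annotation_schema <- function(names = character(0), kinds = character(0)) {
  if (length(names) != length(kinds))
    st_value_error("names and kinds must have equal length")
  if (anyDuplicated(names))
    st_value_error("payload column names must be unique")
  bad <- setdiff(kinds, c("text", "tooltip", "structure_url"))
  if (length(bad))
    st_value_error(sprintf("unknown column kind '%s'", bad[1L]))
  structure(list(columns = data.frame(name = as.character(names),
                                      kind = as.character(kinds),
                                      stringsAsFactors = FALSE)),
            class = "st_annotation_schema")
}

#' Parse a grouped annotation table from JSON
#'
#' The annotation JSON is a list of rows; every row is
#' `[group, x_lookup, payload...]`. The first column names the annotation
#' group (multiple groups are permitted; one group is rendered at a time),
#' the second is the lookup value in the x domain, and subsequent values
#' must match the supplied schema, column for column.
#'
#' @param json_text JSON text or a path to a JSON file.
#' @param schema An `st_annotation_schema`.
#' @return An object of class `st_annotations`: a list with `groups`
#'   (group names in first-appearance order), `annotations` (list of
#'   `list(group, x_lookup, payload)` in file order) and the `schema`.
#' @export
parse_annotations <- function(json_text, schema) {
  stopifnot(inherits(schema, "st_annotation_schema"))
  txt <- json_text
  if (length(txt) == 1L && !grepl("[\\[{]", substr(trimws(txt), 1L, 1L)) &&
      file.exists(txt))
    txt <- paste(readLines(txt, warn = FALSE), collapse = "\n")
  rows <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                   error = function(e)
                     st_parse_error(paste0("JSON parse error: ", conditionMessage(e))))
  if (!is.list(rows)) st_schema_error("annotation JSON must be a list of rows")
  n_payload <- nrow(schema$columns)
  anns <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    row <- rows[[i]]
    if (!is.list(row) || length(row) != 2L + n_payload)
      st_schema_error(sprintf(
        "row %d has %d values; expected %d (group, x_lookup, %d payload column(s))",
        i, length(rows[[i]]), 2L + n_payload, n_payload))
    xl <- suppressWarnings(as.numeric(row[[2L]]))
    if (length(xl) != 1L || !is.finite(xl))
      st_value_error(sprintf("row %d: x_lookup is not a finite number", i))
    payload <- row[-(1:2)]
    names(payload) <- schema$columns$name
    for (k in seq_len(n_payload)) {
      if (schema$columns$kind[k] == "structure_url" &&
          (!is.character(payload[[k]]) || !nzchar(payload[[k]])))
        st_value_error(sprintf("row %d: structure-url column '%s' must be non-empty text",
                               i, schema$columns$name[k]))
    }
    anns[[i]] <- list(group = as.character(row[[1L]]), x_lookup = xl,
                      payload = payload)
  }
  groups <- unique(vapply(anns, `[[`, character(1L), "group"))
  structure(list(groups = groups, annotations = anns, schema = schema),
            class = "st_annotations")
}

#' Anchor a group of annotations to data points of a series
#'
#' Each annotation in the group binds to the series point with minimal
#' `|x - x_lookup|`, accepted when that distance is at most
#' `rel_tolerance` times the series' x-extent width (ties between
#' equidistant points break toward the smaller x). Annotations whose lookup
#' value falls farther than the tolerance are reported as unmatched, not
#' fatal.
#'
#' @param set An `st_annotations`.
#' @param group Group name to anchor.
#' @param series An `st_series`.
#' @param rel_tolerance Acceptance radius relative to the series x-extent
#'   width (default 0.005, i.e. 0.5%).
#' @return A list with `matched` (list of `list(annotation, point,
#'   distance)`) and `unmatched` (list of annotations).
#' @export
anchor_annotations <- function(set, group, series, rel_tolerance = 0.005) {
  stopifnot(inherits(set, "st_annotations"), inherits(series, "st_series"))
  if (!group %in% set$groups)
    st_notfound_error(sprintf("no annotation group '%s'", group))
  x <- series$points$x
  if (length(x) == 0L) {
    in_grp <- Filter(function(a) identical(a$group, group), set$annotations)
    return(list(matched = list(), unmatched = in_grp))
  }
  width <- diff(range(x))
  tol <- rel_tolerance * width
  matched <- list(); unmatched <- list()
  for (a in set$annotations) {
    if (!identical(a$group, group)) next
    d <- abs(x - a$x_lookup)
    j <- which(d == min(d))[1L]  # x sorted ascending: first index is smaller x
    if (d[j] <= tol) {
      matched[[length(matched) + 1L]] <-
        list(annotation = a,
             point = list(x = x[j], y = series$points$y[j]),
             distance = d[j])
    } else {
      unmatched[[length(unmatched) + 1L]] <- a
    }
  }
  list(matched = matched, unmatched = unmatched)
}

#' Build tooltip content for one annotation
#'
#' Tooltip-kind payload columns become `"<key>: <value>"` lines;
#' structure-url columns are resolved to molfile text, parsed, and depicted
#' as embeddable SVG fragments. A resolver or parse failure degrades
#' gracefully: the failing column is replaced by an error placeholder line
#' and the remaining columns are kept.
#'
#' @param a One annotation (`list(group, x_lookup, payload)`).
#' @param schema The `st_annotation_schema`.
#' @param resolver Function mapping a structure-url value to molfile text.
#' @param mol_size_px Side of the embedded depiction, pixels.
#' @param style An `st_style` passed to [depict()].
#' @return A list with `lines` (character vector of `"<key>: <value>"`
#'   lines), `structures` (list of SVG fragment strings) and `molecules`
#'   (list of parsed `st_molecule`s).
#' @export
build_tooltip <- function(a, schema, resolver = read_text_resolver,
                          mol_size_px = 80L, style = st_style()) {
  lines <- character(0)
  structures <- list()
  molecules <- list()
  cols <- schema$columns
  for (k in seq_len(nrow(cols))) {
    val <- as.character(a$payload[[k]])
    if (cols$kind[k] == "tooltip") {
      lines <- c(lines, paste0(cols$name[k], ": ", val))
    } else if (cols$kind[k] == "structure_url") {
      frag <- tryCatch({
        mol <- parse_molfile(resolver(val))
        molecules[[length(molecules) + 1L]] <- mol
        depict(mol, size_px = mol_size_px, style = style)
      }, st_error = function(e) {
        lines <<- c(lines, paste0(cols$name[k], ": <error: ",
                                  conditionMessage(e), ">"))
        NULL
      })
      if (!is.null(frag)) structures[[length(structures) + 1L]] <- frag
    }
  }
  list(lines = lines, structures = structures, molecules = molecules)
}
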