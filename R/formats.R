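# Serializers for annotation documents: minimal text grammar, CSV
# schema, XML export, and the native KMAP state format. Every format is
# paired with a reader so write -> parse is the identity on the
# information the format carries (the minimal text format is documented
# lossy: it drops value/unit/info fields).

STYLE_KEYS <- c("shape", "size", "fill", "stroke", "stroke_width",
                "opacity", "label")
CSV_STYLE_COLS <- c("shape", "width", "height", "fill", "stroke",
                    "stroke_width", "opacity", "label", "value", "unit")

num_fmt <- function(x) {
  vapply(as.numeric(x), function(v) {
    if (is.na(v)) "" else sprintf("%.15g", v)
  }, character(1))
}

# --- minimal text --------------------------------------------------------

#' Parse the minimal text annotation format
#'
#' Lines starting with `@` are style directives of whitespace-separated
#' `key=value` tokens (`shape`, `size` as `WxH`, `fill`, `stroke`,
#' `stroke_width`, `opacity`, and `label`, which consumes the rest of
#' the line). Every other non-empty, non-`#` line names one kinase and
#' yields one annotation carrying the most recent directive's style;
#' before any directive the default style (red 15 x 15 circle) applies.
#'
#' @param text Document as a single string or character vector of lines.
#' @param index Optional [build_name_index()]; when supplied, kinase
#'   lines are resolved and lines that do not resolve uniquely are
#'   collected in the `unresolved` report instead of the set.
#' @return List with `set` (an [annotation_set()]) and `unresolved`
#'   (data frame `line`, `name`, `reason`). No kinase line is silently
#'   dropped: `length(set) + nrow(unresolved)` equals the number of
#'   kinase lines.
#' @export
#' @examples
#' doc <- "@ shape=square size=25x25 fill=red stroke=grey\nEGFR\nABL1"
#' parse_minimal_text(doc)$set
parse_minimal_text <- function(text, index = NULL) {
  lines <- if (length(text) == 1L) strsplit(text, "\r?\n")[[1]] else text
  style <- default_style()
  anns <- list()
  unres <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, "@")) {
      style <- parse_style_directive(line, i)
      next
    }
    name <- line
    if (is.null(index)) {
      anns[[length(anns) + 1L]] <- annotation(name, style)
    } else {
      res <- resolve_name(name, index)
      if (res$status == "unique") {
        anns[[length(anns) + 1L]] <- annotation(res$match, style)
      } else {
        unres[[length(unres) + 1L]] <- list(line = i, name = name,
                                            reason = res$status)
      }
    }
  }
  report <- if (length(unres) == 0) {
    data.frame(line = integer(0), name = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  } else {
    data.frame(line = vapply(unres, `[[`, numeric(1), "line"),
               name = vapply(unres, `[[`, character(1), "name"),
               reason = vapply(unres, `[[`, character(1), "reason"),
               stringsAsFactors = FALSE)
  }
  list(set = annotation_set(anns), unresolved = report)
}

parse_style_directive <- function(line, lineno) {
  body <- sub("^@\\s*", "", line)
  label <- ""
  m <- regexpr("(^|\\s)label=", body)
  if (m > 0) {
    start <- m + attr(m, "match.length")
    label <- substring(body, start)
    body <- trimws(substring(body, 1, m - 1))
  }
  tokens <- strsplit(trimws(body), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  args <- list(label = label)
  for (tok in tokens) {
    eq <- regexpr("=", tok, fixed = TRUE)
    if (eq < 1) {
      stop(sprintf("line %d: malformed directive token '%s' (expected key=value)",
                   lineno, tok), call. = FALSE)
    }
    key <- substring(tok, 1, eq - 1)
    val <- substring(tok, eq + 1)
    if (!key %in% STYLE_KEYS) {
      stop(sprintf("line %d: unknown style key '%s'", lineno, key),
           call. = FALSE)
    }
    if (key == "size") {
      wh <- strsplit(val, "x", fixed = TRUE)[[1]]
      w <- suppressWarnings(as.numeric(wh[1]))
      h <- suppressWarnings(as.numeric(wh[2]))
      if (length(wh) != 2 || is.na(w) || is.na(h)) {
        stop(sprintf("line %d: malformed size '%s' (expected WxH)",
                     lineno, val), call. = FALSE)
      }
      args$width <- w
      args$height <- h
    } else if (key %in% c("stroke_width", "opacity")) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) {
        stop(sprintf("line %d: non-numeric %s '%s'", lineno, key, val),
             call. = FALSE)
      }
      args[[key]] <- num
    } else {
      args[[key]] <- val
    }
  }
  tryCatch(do.call(annotation_style, args),
           error = function(e) stop(sprintf("line %d: %s", lineno,
                                            conditionMessage(e)),
                                    call. = FALSE))
}

#' Write the minimal text annotation format
#'
#' Emits one style directive per maximal run of consecutive identical
#' styles, followed by the kinase names of that run. The format carries
#' styles only; value, unit and info fields are documented lossiness.
#'
#' @param set An [annotation_set()].
#' @return Document text (single string; empty set gives empty string).
#' @export
write_minimal_text <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  if (length(set$annotations) == 0) return("")
  out <- character(0)
  prev_style <- NULL
  for (ann in set$annotations) {
    if (is.null(prev_style) || !identical(ann$style, prev_style)) {
      out <- c(out, format_style_directive(ann$style))
      prev_style <- ann$style
    }
    out <- c(out, ann$xname)
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

format_style_directive <- function(style) {
  parts <- c(
    paste0("shape=", style$shape),
    paste0("size=", num_fmt(style$width), "x", num_fmt(style$height)),
    paste0("fill=", style$fill),
    paste0("stroke=", style$stroke),
    paste0("stroke_width=", num_fmt(style$stroke_width)),
    paste0("opacity=", num_fmt(style$opacity))
  )
  if (nzchar(style$label)) parts <- c(parts, paste0("label=", style$label))
  paste("@", paste(parts, collapse = " "))
}

# --- CSV -----------------------------------------------------------------

#' Parse the annotation CSV schema
#'
#' Comma-delimited, UTF-8, RFC 4180 quoting, header row. Recognized
#' columns: `xname` (required), the style columns (`shape`, `width`,
#' `height`, `fill`, `stroke`, `stroke_width`, `opacity`, `label`),
#' `value` and `unit`. Any other column is preserved, in header order,
#' into each annotation's `info`. Empty style cells take the default
#' style's field.
#'
#' @param text CSV document as a single string.
#' @return An [annotation_set()].
#' @export
parse_annotation_csv <- function(text) {
  lines <- strsplit(text, "\r?\n")[[1]]
  provenance <- ""
  if (length(lines) > 0 && startsWith(lines[1], "#provenance:")) {
    provenance <- sub("^#provenance: ?", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) == 0 || all(!nzchar(lines))) {
    stop("CSV document has no header row", call. = FALSE)
  }
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        header = TRUE, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  if (!"xname" %in% names(df)) {
    stop("CSV is missing the required 'xname' column", call. = FALSE)
  }
  info_cols <- setdiff(names(df), c("xname", CSV_STYLE_COLS))
  anns <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    anns[[i]] <- row_to_annotation(df[i, , drop = FALSE], i, info_cols)
  }
  annotation_set(anns, provenance = provenance)
}

cell_or <- function(row, col, default) {
  if (!col %in% names(row)) return(default)
  v <- row[[col]]
  if (is.na(v) || !nzchar(v)) default else v
}

row_to_annotation <- function(row, rowno, info_cols) {
  d <- default_style()
  xname <- cell_or(row, "xname", "")
  if (!nzchar(xname)) {
    stop(sprintf("row %d: empty xname", rowno), call. = FALSE)
  }
  style <- tryCatch(
    annotation_style(
      shape = cell_or(row, "shape", d$shape),
      width = cell_or(row, "width", d$width),
      height = cell_or(row, "height", d$height),
      fill = cell_or(row, "fill", d$fill),
      stroke = cell_or(row, "stroke", d$stroke),
      stroke_width = cell_or(row, "stroke_width", d$stroke_width),
      opacity = cell_or(row, "opacity", d$opacity),
      label = cell_or(row, "label", "")
    ),
    error = function(e) stop(sprintf("row %d: %s", rowno,
                                     conditionMessage(e)), call. = FALSE))
  raw_value <- cell_or(row, "value", "")
  value <- NA_real_
  if (nzchar(raw_value)) {
    value <- suppressWarnings(as.numeric(raw_value))
    if (is.na(value)) {
      stop(sprintf("row %d: non-numeric value '%s'", rowno, raw_value),
           call. = FALSE)
    }
  }
  info <- character(0)
  for (col in info_cols) {
    v <- row[[col]]
    if (!is.na(v) && nzchar(v)) info[[col]] <- v
  }
  annotation(xname, style, value = value,
             unit = cell_or(row, "unit", ""), info = info)
}

#' Write the annotation CSV schema
#'
#' Inverse of [parse_annotation_csv()]: the round trip is exact,
#' including the order of info columns (union of info keys in first
#' appearance order).
#'
#' @param set An [annotation_set()].
#' @return CSV document as a single string.
#' @export
write_annotation_csv <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  info_cols <- order_info_columns(set)
  header <- c("xname", CSV_STYLE_COLS, info_cols)
  rows <- vapply(set$annotations, function(ann) {
    sty <- ann$style
    cells <- c(ann$xname, sty$shape, num_fmt(sty$width),
               num_fmt(sty$height), sty$fill, sty$stroke,
               num_fmt(sty$stroke_width), num_fmt(sty$opacity),
               sty$label, num_fmt(ann$value), ann$unit,
               vapply(info_cols, function(k) {
                 if (k %in% names(ann$info)) ann$info[[k]] else ""
               }, character(1)))
    paste(csv_quote(cells), collapse = ",")
  }, character(1))
  body <- paste(c(paste(csv_quote(header), collapse = ","), rows),
                collapse = "\n")
  prov <- if (nzchar(set$provenance)) {
    paste0("#provenance: ", set$provenance, "\n")
  } else ""
  paste0(prov, body, "\n")
}

# Global info-column order: a topological merge of the per-annotation
# key orders (ties broken by first appearance), so that a set whose
# annotations agree on relative key order round-trips through the
# columnar CSV with every annotation's own order intact. Conflicting
# orders fall back to first appearance for the contested keys.
order_info_columns <- function(set) {
  keys <- character(0)
  edges <- list()
  for (ann in set$annotations) {
    kn <- names(ann$info)
    keys <- union(keys, kn)
    if (length(kn) > 1) {
      for (j in seq_len(length(kn) - 1)) {
        edges[[length(edges) + 1L]] <- c(kn[j], kn[j + 1])
      }
    }
  }
  if (length(keys) <= 1) return(keys)
  before <- lapply(stats::setNames(keys, keys), function(k) character(0))
  for (e in edges) {
    before[[e[2]]] <- union(before[[e[2]]], e[1])
  }
  out <- character(0)
  remaining <- keys
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(k) {
      all(!before[[k]] %in% remaining)
    }, logical(1))]
    if (length(ready) == 0) ready <- remaining[1]  # cycle: first appearance
    pick <- ready[1]
    out <- c(out, pick)
    remaining <- setdiff(remaining, pick)
  }
  out
}

csv_quote <- function(x) {
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

# --- XML -----------------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Write annotations as XML
#'
#' One `<annotation>` element per annotation with attributes mirroring
#' the CSV columns; info entries become `<info key="...">` child
#' elements (info keys such as `"Kd(nM)"` are not valid XML attribute
#' names). [parse_annotation_xml()] round-trips the set.
#'
#' @param set An [annotation_set()].
#' @return XML document as a single string.
#' @export
write_annotation_xml <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           sprintf('<annotation_set provenance="%s">',
                   xml_escape(set$provenance)))
  for (ann in set$annotations) {
    sty <- ann$style
    attrs <- sprintf(
      'xname="%s" shape="%s" width="%s" height="%s" fill="%s" stroke="%s" stroke_width="%s" opacity="%s" label="%s" value="%s" unit="%s"',
      xml_escape(ann$xname), sty$shape, num_fmt(sty$width),
      num_fmt(sty$height), sty$fill, sty$stroke,
      num_fmt(sty$stroke_width), num_fmt(sty$opacity),
      xml_escape(sty$label), num_fmt(ann$value), xml_escape(ann$unit))
    if (length(ann$info) == 0) {
      out <- c(out, sprintf("  <annotation %s/>", attrs))
    } else {
      out <- c(out, sprintf("  <annotation %s>", attrs))
      for (k in names(ann$info)) {
        out <- c(out, sprintf('    <info key="%s">%s</info>',
                              xml_escape(k), xml_escape(ann$info[[k]])))
      }
      out <- c(out, "  </annotation>")
    }
  }
  out <- c(out, "</annotation_set>")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Parse the annotation XML export
#'
#' @param text XML document as a single string.
#' @return An [annotation_set()].
#' @export
parse_annotation_xml <- function(text) {
  doc <- xml2::read_xml(text)
  if (xml2::xml_name(doc) != "annotation_set") {
    stop("expected an <annotation_set> root element", call. = FALSE)
  }
  provenance <- xml2::xml_attr(doc, "provenance")
  if (is.na(provenance)) provenance <- ""
  nodes <- xml2::xml_find_all(doc, "./annotation")
  anns <- lapply(nodes, function(node) {
    a <- function(name, default = "") {
      v <- xml2::xml_attr(node, name)
      if (is.na(v) || !nzchar(v)) default else v
    }
    d <- default_style()
    style <- annotation_style(
      shape = a("shape", d$shape), width = a("width", d$width),
      height = a("height", d$height), fill = a("fill", d$fill),
      stroke = a("stroke", d$stroke),
      stroke_width = a("stroke_width", d$stroke_width),
      opacity = a("opacity", d$opacity), label = a("label", ""))
    raw_value <- a("value", "")
    value <- if (nzchar(raw_value)) as.numeric(raw_value) else NA_real_
    info_nodes <- xml2::xml_find_all(node, "./info")
    info <- stats::setNames(xml2::xml_text(info_nodes),
                            xml2::xml_attr(info_nodes, "key"))
    annotation(a("xname"), style, value = value, unit = a("unit", ""),
               info = info)
  })
  annotation_set(anns, provenance = provenance)
}

# --- KMAP (native state document) ---------------------------------------

VISIBLE_COMPONENTS <- c("branches", "group_labels", "kinase_labels",
                        "legend", "atypical_panel")
KMAP_VERSION <- 1L
KMAP_FIELDS <- c("schema_version", "provenance", "annotations",
                 "label_font", "zoom", "visible_components", "interactive")

#' Construct a map state
#'
#' A map state reproduces a complete view: the annotation set plus
#' label font, zoom level, which tree components are visible, and
#' whether tooltip metadata is embedded (interactive mode).
#'
#' @param annotations An [annotation_set()].
#' @param label_font List with `name` (font family) and `size` (points).
#' @param zoom Positive zoom factor.
#' @param visible_components Subset of `"branches"`, `"group_labels"`,
#'   `"kinase_labels"`, `"legend"`, `"atypical_panel"`.
#' @param interactive Embed tooltip metadata in rendered SVG?
#' @return A `map_state` object.
#' @export
map_state <- function(annotations = annotation_set(),
                      label_font = list(name = "sans-serif", size = 10),
                      zoom = 1,
                      visible_components = VISIBLE_COMPONENTS,
                      interactive = FALSE) {
  stopifnot(inherits(annotations, "annotation_set"))
  zoom <- as.numeric(zoom)[1]
  if (!is.finite(zoom) || zoom <= 0) stop("zoom must be > 0", call. = FALSE)
  vc <- unique(as.character(visible_components))
  bad <- setdiff(vc, VISIBLE_COMPONENTS)
  if (length(bad) > 0) {
    stop("unknown visible component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  vc <- VISIBLE_COMPONENTS[VISIBLE_COMPONENTS %in% vc]
  if (!is.list(label_font) || is.null(label_font$name) ||
      is.null(label_font$size)) {
    stop("label_font must be a list with 'name' and 'size'", call. = FALSE)
  }
  structure(list(annotations = annotations,
                 label_font = list(name = as.character(label_font$name)[1],
                                   size = as.numeric(label_font$size)[1]),
                 zoom = zoom,
                 visible_components = vc,
                 interactive = isTRUE(interactive)),
            class = "map_state")
}

annotation_to_list <- function(ann) {
  sty <- ann$style
  list(xname = ann$xname, shape = sty$shape, width = sty$width,
       height = sty$height, fill = sty$fill, stroke = sty$stroke,
       stroke_width = sty$stroke_width, opacity = sty$opacity,
       label = sty$label,
       value = if (is.na(ann$value)) NULL else ann$value,
       unit = ann$unit,
       info = if (length(ann$info)) as.list(ann$info) else NULL)
}

list_to_annotation <- function(x, idx) {
  if (is.null(x$xname)) {
    stop(sprintf("annotation %d: missing xname", idx), call. = FALSE)
  }
  d <- default_style()
  pick <- function(name, default) if (is.null(x[[name]])) default else x[[name]]
  style <- annotation_style(
    shape = pick("shape", d$shape), width = pick("width", d$width),
    height = pick("height", d$height), fill = pick("fill", d$fill),
    stroke = pick("stroke", d$stroke),
    stroke_width = pick("stroke_width", d$stroke_width),
    opacity = pick("opacity", d$opacity), label = pick("label", ""))
  info <- character(0)
  if (!is.null(x$info)) {
    info <- stats::setNames(vapply(x$info, as.character, character(1)),
                            names(x$info))
  }
  annotation(x$xname, style,
             value = if (is.null(x$value)) NA_real_ else as.numeric(x$value),
             unit = pick("unit", ""), info = info)
}

#' Write the native KMAP state document
#'
#' A versioned JSON document preserving the metadata needed to exactly
#' reproduce a view: annotations (in the CSV schema's field names),
#' label font, zoom, component visibility and interactive mode.
#'
#' @param state A [map_state()].
#' @return KMAP document as a single string.
#' @export
write_kmap <- function(state) {
  stopifnot(inherits(state, "map_state"))
  payload <- list(
    schema_version = KMAP_VERSION,
    provenance = state$annotations$provenance,
    annotations = lapply(state$annotations$annotations, annotation_to_list),
    label_font = state$label_font,
    zoom = state$zoom,
    visible_components = as.list(state$visible_components),
    interactive = state$interactive
  )
  paste0(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE), "\n")
}

#' Parse the native KMAP state document
#'
#' Strict schema: unknown top-level fields are rejected, and any
#' `schema_version` other than 1 raises an unsupported-version error.
#'
#' @param text KMAP document as a single string.
#' @return A [map_state()].
#' @export
parse_kmap <- function(text) {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) stop("invalid KMAP document: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  if (!is.list(doc) || is.null(names(doc))) {
    stop("invalid KMAP document: expected a top-level object",
         call. = FALSE)
  }
  unknown <- setdiff(names(doc), KMAP_FIELDS)
  if (length(unknown) > 0) {
    stop("unknown KMAP field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(doc$schema_version)) {
    stop("KMAP document is missing schema_version", call. = FALSE)
  }
  if (!identical(as.numeric(doc$schema_version), as.numeric(KMAP_VERSION))) {
    stop("unsupported KMAP schema_version: ", doc$schema_version,
         call. = FALSE)
  }
  anns <- list()
  if (!is.null(doc$annotations)) {
    anns <- lapply(seq_along(doc$annotations), function(i) {
      list_to_annotation(doc$annotations[[i]], i)
    })
  }
  set <- annotation_set(anns, provenance = if (is.null(doc$provenance)) ""
                        else doc$provenance)
  map_state(
    annotations = set,
    label_font = if (is.null(doc$label_font)) {
      list(name = "sans-serif", size = 10)
    } else doc$label_font,
    zoom = if (is.null(doc$zoom)) 1 else doc$zoom,
    visible_components = if (is.null(doc$visible_components)) {
      VISIBLE_COMPONENTS
    } else unlist(doc$visible_components, use.names = FALSE),
    interactive = isTRUE(doc$interactive)
  )
}
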