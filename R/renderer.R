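# SVG renderer: turns a map state + layout + kinome table into a
# deterministic, publication-quality vector image. Fonts are referenced
# by family name only and label widths are never measured, so the same
# scene renders to a byte-identical document on every platform.

fmt3 <- function(v) sprintf("%.3f", round(as.numeric(v), 3))

#' Build legend entries from an annotation set
#'
#' One entry per distinct marker style, in order of first appearance.
#' Captions come from the styles' labels, from the supplied caption
#' mapping, or fall back to `"style N"`.
#'
#' @param set An [annotation_set()].
#' @param captions Named character vector mapping a style label (or the
#'   fallback key `"style N"`) to a caption.
#' @return List of entries, each a list with `style` and `caption`.
#' @export
build_legend <- function(set, captions = character(0)) {
  stopifnot(inherits(set, "annotation_set"))
  entries <- list()
  seen <- list()
  for (ann in set$annotations) {
    dup <- any(vapply(seen, identical, logical(1), ann$style))
    if (dup) next
    seen[[length(seen) + 1L]] <- ann$style
    n <- length(entries) + 1L
    key <- if (nzchar(ann$style$label)) ann$style$label else sprintf("style %d", n)
    caption <- if (key %in% names(captions)) {
      captions[[key]]
    } else if (nzchar(ann$style$label)) {
      ann$style$label
    } else {
      sprintf("style %d", n)
    }
    entries[[n]] <- list(style = ann$style, caption = caption)
  }
  entries
}

marker_svg <- function(style, cx, cy, tooltip = NULL) {
  w <- style$width; h <- style$height
  paint <- sprintf('fill="%s" fill-opacity="%s" stroke="%s" stroke-width="%s"',
                   style$fill, fmt3(style$opacity), style$stroke,
                   fmt3(style$stroke_width))
  shape <- switch(style$shape,
    circle = if (w == h) {
      sprintf('<circle cx="%s" cy="%s" r="%s" %s/>',
              fmt3(cx), fmt3(cy), fmt3(w / 2), paint)
    } else {
      sprintf('<ellipse cx="%s" cy="%s" rx="%s" ry="%s" %s/>',
              fmt3(cx), fmt3(cy), fmt3(w / 2), fmt3(h / 2), paint)
    },
    square = sprintf('<rect x="%s" y="%s" width="%s" height="%s" %s/>',
                     fmt3(cx - w / 2), fmt3(cy - h / 2), fmt3(w), fmt3(h),
                     paint),
    triangle = polygon_svg(triangle_points(cx, cy, w, h), paint),
    diamond = polygon_svg(diamond_points(cx, cy, w, h), paint),
    star = polygon_svg(star_points(cx, cy, w, h), paint),
    stop("unknown shape: ", style$shape, call. = FALSE))
  if (is.null(tooltip)) return(shape)
  # wrap so the <title> binds to this marker only
  sprintf("<g>%s<title>%s</title></g>", shape, xml_escape(tooltip))
}

polygon_svg <- function(pts, paint) {
  sprintf('<polygon points="%s" %s/>',
          paste(sprintf("%s,%s", fmt3(pts[, 1]), fmt3(pts[, 2])),
                collapse = " "), paint)
}

triangle_points <- function(cx, cy, w, h) {
  matrix(c(cx, cy - h / 2,
           cx - w / 2, cy + h / 2,
           cx + w / 2, cy + h / 2), ncol = 2, byrow = TRUE)
}

diamond_points <- function(cx, cy, w, h) {
  matrix(c(cx, cy - h / 2,
           cx + w / 2, cy,
           cx, cy + h / 2,
           cx - w / 2, cy), ncol = 2, byrow = TRUE)
}

star_points <- function(cx, cy, w, h, inner = 0.5) {
  angles <- pi / 2 + (0:9) * pi / 5
  radii <- rep(c(1, inner), 5)
  cbind(cx + radii * (w / 2) * cos(angles),
        cy - radii * (h / 2) * sin(angles))
}

#' Render an annotated kinome map as SVG
#'
#' Draws, in z-order: branches, group labels, kinase labels, the
#' atypical side panel, annotation markers (annotation-set order, so
#' later annotations draw on top), then the legend. Markers are
#' centered on their kinase's position; multiple markers on one kinase
#' are offset on a small ring (radius = half the largest marker width
#' at that kinase) so each stays distinguishable. When the state is
#' interactive, every marker carries an SVG `<title>` tooltip holding
#' the annotation's info fields as `key: value` lines. Components
#' toggled off are absent from the document, not hidden. Output is
#' deterministic: the same scene renders byte-identically.
#'
#' @param state A [map_state()].
#' @param layout A [layout_kinome()] result covering every annotated
#'   kinase.
#' @param table The [kinome_table()] the layout was computed from.
#' @param title Optional figure title.
#' @param legend Optional [build_legend()] entries; when `NULL` and the
#'   legend component is visible, the legend is built from the state's
#'   annotations.
#' @return SVG 1.1 document as a single string.
#' @export
#' @examples
#' kin <- load_kinome()
#' set <- parse_minimal_text("@ shape=square size=25x25 fill=red stroke=grey\nEGFR")$set
#' svg <- render_svg(map_state(set), layout_kinome(kin), kin)
render_svg <- function(state, layout, table, title = NULL, legend = NULL) {
  stopifnot(inherits(state, "map_state"),
            inherits(layout, "kinome_layout"),
            inherits(table, "kinome_table"))
  vis <- state$visible_components
  cfg <- layout$config
  font <- state$label_font
  lp <- layout$leaf_positions

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%s" height="%s" viewBox="0 0 %s %s">'),
            fmt3(cfg$canvas_width), fmt3(cfg$canvas_height),
            fmt3(cfg$canvas_width), fmt3(cfg$canvas_height)),
    sprintf('<g class="root" transform="scale(%s)">', fmt3(state$zoom))
  )
  if (!is.null(title) && nzchar(title)) {
    out <- c(out, sprintf(
      '<text class="title" x="%s" y="%s" font-family="%s" font-size="%s" text-anchor="middle">%s</text>',
      fmt3(cfg$canvas_width / 2), fmt3(font$size * 2),
      xml_escape(font$name), fmt3(font$size * 1.6), xml_escape(title)))
  }

  if ("branches" %in% vis) {
    out <- c(out, '<g class="branches" fill="none" stroke="#B0B0B0" stroke-width="1">')
    for (p in layout$branch_paths) {
      out <- c(out, sprintf('<polyline points="%s"/>',
                            paste(sprintf("%s,%s", fmt3(p[, "x"]),
                                          fmt3(p[, "y"])),
                                  collapse = " ")))
    }
    out <- c(out, "</g>")
  }

  if ("group_labels" %in% vis && nrow(layout$group_anchors) > 0) {
    out <- c(out, '<g class="group-labels">')
    ga <- layout$group_anchors
    for (i in seq_len(nrow(ga))) {
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-family="%s" font-size="%s" font-weight="bold" text-anchor="middle">%s</text>',
        fmt3(ga$x[i]), fmt3(ga$y[i]), xml_escape(font$name),
        fmt3(font$size * 1.4), xml_escape(ga$label[i])))
    }
    out <- c(out, "</g>")
  }

  typical_names <- table$xname[table$group != "Atypical"]
  if ("kinase_labels" %in% vis && nrow(layout$label_anchors) > 0) {
    la <- layout$label_anchors[layout$label_anchors$xname %in% typical_names, ,
                               drop = FALSE]
    out <- c(out, '<g class="kinase-labels">')
    for (i in seq_len(nrow(la))) {
      anchor <- if (la$rotation[i] > 90 && la$rotation[i] < 270) "end" else "start"
      rot <- la$rotation[i]
      if (anchor == "end") rot <- rot - 180
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-family="%s" font-size="%s" text-anchor="%s" transform="rotate(%s %s %s)">%s</text>',
        fmt3(la$x[i]), fmt3(la$y[i]), xml_escape(font$name),
        fmt3(font$size), anchor, fmt3(rot), fmt3(la$x[i]), fmt3(la$y[i]),
        xml_escape(la$xname[i])))
    }
    out <- c(out, "</g>")
  }

  if ("atypical_panel" %in% vis &&
      (nrow(layout$family_anchors) > 0 || any(!lp$xname %in% typical_names))) {
    out <- c(out, '<g class="atypical-panel">')
    fa <- layout$family_anchors
    for (i in seq_len(nrow(fa))) {
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-family="%s" font-size="%s" font-weight="bold">%s</text>',
        fmt3(fa$x[i]), fmt3(fa$y[i]), xml_escape(font$name),
        fmt3(font$size * 1.1), xml_escape(fa$family[i])))
    }
    if ("kinase_labels" %in% vis) {
      la <- layout$label_anchors[!layout$label_anchors$xname %in% typical_names, ,
                                 drop = FALSE]
      for (i in seq_len(nrow(la))) {
        out <- c(out, sprintf(
          '<text x="%s" y="%s" font-family="%s" font-size="%s">%s</text>',
          fmt3(la$x[i]), fmt3(la$y[i]), xml_escape(font$name),
          fmt3(font$size), xml_escape(la$xname[i])))
      }
    }
    out <- c(out, "</g>")
  }

  # markers: annotation order is document order (later draws on top)
  anns <- state$annotations$annotations
  if (length(anns) > 0) {
    xnames <- vapply(anns, `[[`, character(1), "xname")
    missing <- setdiff(unique(xnames), lp$xname)
    if (length(missing) > 0) {
      stop("no layout position for kinase(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    per_kinase <- table(xnames)
    seen_count <- stats::setNames(integer(length(per_kinase)),
                                  names(per_kinase))
    ring_radius <- vapply(names(per_kinase), function(xn) {
      max(vapply(anns[xnames == xn], function(a) a$style$width,
                 numeric(1))) / 2
    }, numeric(1))
    out <- c(out, '<g class="markers">')
    for (ann in anns) {
      j <- match(ann$xname, lp$xname)
      cx <- lp$x[j]; cy <- lp$y[j]
      m <- per_kinase[[ann$xname]]
      if (m > 1) {
        k <- seen_count[[ann$xname]]
        theta <- 2 * pi * k / m
        r <- ring_radius[[ann$xname]]
        cx <- cx + r * cos(theta)
        cy <- cy - r * sin(theta)
      }
      seen_count[[ann$xname]] <- seen_count[[ann$xname]] + 1L
      tooltip <- NULL
      if (state$interactive) {
        tooltip <- if (length(ann$info) > 0) {
          paste(sprintf("%s: %s", names(ann$info), ann$info),
                collapse = "\n")
        } else {
          ann$xname
        }
      }
      out <- c(out, marker_svg(ann$style, cx, cy, tooltip))
      if (nzchar(ann$style$label)) {
        out <- c(out, sprintf(
          '<text x="%s" y="%s" font-family="%s" font-size="%s" text-anchor="middle">%s</text>',
          fmt3(cx), fmt3(cy + ann$style$height / 2 + font$size),
          xml_escape(font$name), fmt3(font$size),
          xml_escape(ann$style$label)))
      }
    }
    out <- c(out, "</g>")
  }

  if ("legend" %in% vis) {
    if (is.null(legend)) legend <- build_legend(state$annotations)
    if (length(legend) > 0) {
      out <- c(out, '<g class="legend">')
      x0 <- 20; y0 <- cfg$canvas_height - 20 * length(legend) - 20
      for (i in seq_along(legend)) {
        e <- legend[[i]]
        sw <- e$style
        sw$width <- min(sw$width, 14)
        sw$height <- min(sw$height, 14)
        y <- y0 + 20 * (i - 1)
        out <- c(out, marker_svg(sw, x0, y),
                 sprintf('<text x="%s" y="%s" font-family="%s" font-size="%s" dominant-baseline="middle">%s</text>',
                         fmt3(x0 + 14), fmt3(y + font$size * 0.35),
                         xml_escape(font$name), fmt3(font$size),
                         xml_escape(e$caption)))
      }
      out <- c(out, "</g>")
    }
  }

  out <- c(out, "</g>", "</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Pixel dimensions of a rasterized canvas
#'
#' @param canvas_width,canvas_height Canvas size in CSS pixels (96 dpi).
#' @param dpi Target resolution in dots per inch.
#' @return Integer vector `c(width, height)` = canvas size x dpi / 96,
#'   rounded to the nearest integer.
#' @export
png_dimensions <- function(canvas_width, canvas_height, dpi = 96) {
  if (!is.finite(dpi) || dpi <= 0) stop("dpi must be > 0", call. = FALSE)
  c(width = as.integer(round(canvas_width * dpi / 96)),
    height = as.integer(round(canvas_height * dpi / 96)))
}

find_raster_backend <- function() {
  if (requireNamespace("rsvg", quietly = TRUE)) return("rsvg")
  for (tool in c("rsvg-convert", "cairosvg", "inkscape", "convert")) {
    if (nzchar(Sys.which(tool))) return(tool)
  }
  NULL
}

#' Rasterize an SVG document to PNG
#'
#' Optional capability: SVG is the canonical output and PNG export
#' requires a rasterization backend (the `rsvg` package or an
#' `rsvg-convert`/`cairosvg`/`inkscape`/ImageMagick binary on the
#' PATH). Without one, an explicit capability error is raised and no
#' file is written. Pixel dimensions follow [png_dimensions()].
#'
#' @param svg SVG document text from [render_svg()].
#' @param path Output PNG path.
#' @param dpi Target resolution (96 reproduces the canvas 1:1).
#' @return `path`, invisibly.
#' @export
rasterize_png <- function(svg, path, dpi = 96) {
  doc <- tryCatch(xml2::read_xml(svg),
                  error = function(e) stop("invalid SVG input: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  w <- as.numeric(xml2::xml_attr(doc, "width"))
  h <- as.numeric(xml2::xml_attr(doc, "height"))
  if (is.na(w) || is.na(h)) {
    stop("invalid SVG input: missing width/height", call. = FALSE)
  }
  dims <- png_dimensions(w, h, dpi)
  backend <- find_raster_backend()
  if (is.null(backend)) {
    stop(paste0("PNG export needs a rasterization backend (rsvg R package ",
                "or rsvg-convert/cairosvg/inkscape/convert on the PATH); ",
                "none is available"), call. = FALSE)
  }
  tmp <- tempfile(fileext = ".svg")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(svg, tmp, useBytes = TRUE)
  if (backend == "rsvg") {
    rsvg::rsvg_png(tmp, path, width = dims[["width"]],
                   height = dims[["height"]])
  } else {
    args <- switch(backend,
      "rsvg-convert" = c("-w", dims[["width"]], "-h", dims[["height"]],
                         "-o", path, tmp),
      "cairosvg" = c(tmp, "-o", path, "--output-width", dims[["width"]],
                     "--output-height", dims[["height"]]),
      "inkscape" = c(tmp, "--export-type=png",
                     paste0("--export-filename=", path),
                     paste0("--export-width=", dims[["width"]])),
      "convert" = c("-density", dpi, tmp,
                    "-resize", sprintf("%dx%d", dims[["width"]],
                                       dims[["height"]]), path))
    status <- system2(backend, as.character(args))
    if (status != 0) stop("rasterization backend failed", call. = FALSE)
  }
  invisible(path)
}
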