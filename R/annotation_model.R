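# Annotation model: marker styles, per-kinase annotations, ordered
# annotation sets, and bioactivity-driven size rescaling.

ANNOTATION_SHAPES <- c("circle", "square", "triangle", "diamond", "star")

#' Normalize a color to #RRGGBB
#'
#' Accepts CSS/R named colors or `#RRGGBB`; the literal `"none"` passes
#' through. Output is always upper-case `#RRGGBB` so serialized
#' documents are bit-stable.
#'
#' @param x Character vector of colors.
#' @return Character vector of `#RRGGBB` strings (or `"none"`).
#' @export
normalize_color <- function(x) {
  vapply(as.character(x), function(col) {
    if (is.na(col) || !nzchar(col)) return("none")
    if (identical(tolower(col), "none")) return("none")
    if (grepl("^#[0-9a-fA-F]{6}$", col)) return(toupper(col))
    rgb <- tryCatch(grDevices::col2rgb(col),
                    error = function(e) stop("unknown color: ", col,
                                             call. = FALSE))
    sprintf("#%02X%02X%02X", rgb[1], rgb[2], rgb[3])
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a marker style
#'
#' @param shape One of `"circle"`, `"square"`, `"triangle"`,
#'   `"diamond"`, `"star"`.
#' @param width,height Marker size in pixels, in `(0, 200]`.
#' @param fill,stroke Colors (named or `#RRGGBB`; `"none"` allowed),
#'   normalized to `#RRGGBB`.
#' @param stroke_width Stroke width in pixels, `>= 0`.
#' @param opacity Fill opacity in `[0, 1]`.
#' @param label Optional free-text label (empty string for none).
#' @return An `annotation_style` object.
#' @export
#' @examples
#' annotation_style("square", 25, 25, fill = "red", stroke = "grey")
annotation_style <- function(shape = "circle", width = 15, height = 15,
                             fill = "red", stroke = "none",
                             stroke_width = 1, opacity = 1, label = "") {
  shape <- as.character(shape)[1]
  if (!shape %in% ANNOTATION_SHAPES) {
    stop("unknown shape: ", shape, " (allowed: ",
         paste(ANNOTATION_SHAPES, collapse = ", "), ")", call. = FALSE)
  }
  width <- as.numeric(width)[1]; height <- as.numeric(height)[1]
  stroke_width <- as.numeric(stroke_width)[1]
  opacity <- as.numeric(opacity)[1]
  if (!is.finite(width) || width <= 0 || width > 200 ||
      !is.finite(height) || height <= 0 || height > 200) {
    stop("width and height must lie in (0, 200]", call. = FALSE)
  }
  if (!is.finite(stroke_width) || stroke_width < 0) {
    stop("stroke_width must be >= 0", call. = FALSE)
  }
  if (!is.finite(opacity) || opacity < 0 || opacity > 1) {
    stop("opacity must lie in [0, 1]", call. = FALSE)
  }
  structure(list(shape = shape, width = width, height = height,
                 fill = normalize_color(fill),
                 stroke = normalize_color(stroke),
                 stroke_width = stroke_width, opacity = opacity,
                 label = as.character(label)[1]),
            class = "annotation_style")
}

#' Default marker style
#'
#' Circle, 15 x 15 px, red fill, no stroke — the style applied to
#' kinase lines before any directive.
#'
#' @return An [annotation_style()].
#' @export
default_style <- function() annotation_style()

#' Construct an annotation (one marker on the tree)
#'
#' @param xname Kinase display identifier the marker attaches to.
#' @param style An [annotation_style()].
#' @param value Optional numeric value (e.g. an inhibition constant or a
#'   count); `NA` for none.
#' @param unit Unit tag for `value` (free text, empty for none).
#' @param info Named character vector of extra fields; order is
#'   preserved and rendered into tooltips.
#' @return An `annotation` object.
#' @export
annotation <- function(xname, style = default_style(), value = NA_real_,
                       unit = "", info = character(0)) {
  stopifnot(inherits(style, "annotation_style"))
  xname <- as.character(xname)[1]
  if (is.na(xname) || !nzchar(xname)) {
    stop("annotation needs a non-empty xname", call. = FALSE)
  }
  info_names <- names(info)
  info <- as.character(info)
  if (length(info) > 0) {
    if (is.null(info_names) || any(!nzchar(info_names))) {
      stop("info must be a named character vector", call. = FALSE)
    }
    names(info) <- info_names
  }
  structure(list(xname = xname, style = style,
                 value = as.numeric(value)[1],
                 unit = as.character(unit)[1],
                 info = info),
            class = "annotation")
}

#' Construct an ordered annotation set
#'
#' @param annotations List of [annotation()] objects; order is
#'   meaningful and preserved by every serializer. Multiple annotations
#'   per kinase are allowed.
#' @param provenance Free-text provenance note.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(annotations = list(), provenance = "") {
  if (!all(vapply(annotations, inherits, logical(1), "annotation"))) {
    stop("annotations must be a list of annotation objects", call. = FALSE)
  }
  structure(list(annotations = unname(annotations),
                 provenance = as.character(provenance)[1]),
            class = "annotation_set")
}

#' @export
length.annotation_set <- function(x) length(x$annotations)

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("Annotation set: %d annotation(s) on %d kinase(s)\n",
              length(x$annotations),
              length(unique(vapply(x$annotations, `[[`, character(1),
                                   "xname")))))
  invisible(x)
}

#' Define a marker size scale
#'
#' @param s_min,s_max Output size range in pixels, `0 < s_min <= s_max`.
#' @param transform `"linear"` or `"log10"` (log10 requires all scaled
#'   values to be positive).
#' @param invert If `TRUE` the mapping is reversed so the largest value
#'   receives `s_min` — appropriate for lower-is-stronger metrics such
#'   as dissociation constants.
#' @return A `size_scale` object.
#' @export
size_scale <- function(s_min = 10, s_max = 30, transform = "linear",
                       invert = FALSE) {
  s_min <- as.numeric(s_min)[1]; s_max <- as.numeric(s_max)[1]
  if (!is.finite(s_min) || s_min <= 0) stop("s_min must be > 0", call. = FALSE)
  if (!is.finite(s_max) || s_max < s_min) {
    stop("s_max must be >= s_min", call. = FALSE)
  }
  transform <- match.arg(transform, c("linear", "log10"))
  structure(list(s_min = s_min, s_max = s_max, transform = transform,
                 invert = isTRUE(invert)),
            class = "size_scale")
}

#' Rescale marker sizes from annotation values
#'
#' Maps each annotation's value through the scale's transform `t`
#' (identity or log10) onto `[s_min, s_max]`:
#' `size = s_min + (t(v) - t_min) / (t_max - t_min) * (s_max - s_min)`,
#' setting both width and height. Under `invert` the mapping is
#' reversed. When all values are equal every size is the midpoint
#' `(s_min + s_max) / 2`. Annotations without a value pass through
#' unchanged. The input set is not modified.
#'
#' @param set An [annotation_set()].
#' @param scale A [size_scale()].
#' @return A new [annotation_set()] with rescaled marker sizes.
#' @export
#' @examples
#' sty <- annotation_style()
#' set <- annotation_set(list(
#'   annotation("EGFR", sty, value = 1),
#'   annotation("ABL1", sty, value = 10),
#'   annotation("SRC", sty, value = 100)))
#' rescale_sizes(set, size_scale(10, 30, "log10"))
rescale_sizes <- function(set, scale) {
  stopifnot(inherits(set, "annotation_set"), inherits(scale, "size_scale"))
  vals <- vapply(set$annotations, `[[`, numeric(1), "value")
  in_scope <- !is.na(vals)
  if (!any(in_scope)) return(set)
  v <- vals[in_scope]
  if (scale$transform == "log10") {
    if (any(v <= 0)) {
      bad <- vapply(set$annotations[in_scope][v <= 0], `[[`, character(1),
                    "xname")
      stop("log10 scaling requires positive values; offending kinase(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    t_v <- log10(v)
  } else {
    t_v <- v
  }
  rng <- range(t_v)
  sizes <- if (diff(rng) == 0) {
    rep((scale$s_min + scale$s_max) / 2, length(t_v))
  } else {
    frac <- (t_v - rng[1]) / (rng[2] - rng[1])
    if (scale$invert) frac <- 1 - frac
    scale$s_min + frac * (scale$s_max - scale$s_min)
  }
  out <- set
  k <- 0L
  for (i in seq_along(out$annotations)) {
    if (!in_scope[i]) next
    k <- k + 1L
    sty <- out$annotations[[i]]$style
    sty$width <- sizes[k]
    sty$height <- sizes[k]
    out$annotations[[i]]$style <- sty
  }
  out
}
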