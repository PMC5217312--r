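# Deterministic radial layout of the kinome classification hierarchy.
# The tree is drawn from the classification (group/family/subfamily),
# not from sequence distances: angular spans are allocated
# proportionally to subtree leaf counts, with a fixed gap between
# groups. Atypical kinases are laid out in a side panel grid, apart
# from the main circle, as on the classic kinome poster.

#' Layout configuration
#'
#' @param canvas_width,canvas_height Canvas size in pixels.
#' @param tree_radius Leaf circle radius in pixels.
#' @param group_gap Angular gap between adjacent groups, radians >= 0.
#' @param start_angle Angle of the first group's span start, radians
#'   (angle 0 at the positive x axis, counter-clockwise in mathematical
#'   convention before the y flip to SVG's y-down coordinates).
#' @param level_radii Named fractions of `tree_radius` for the anchor
#'   radius of each hierarchy level; must be strictly increasing from
#'   `root` (0) to `kinase` (1).
#' @param atypical_panel List with the panel rectangle `x`, `y`, `w`,
#'   `h` (pixels) and grid `cell` size.
#' @param label_offset Pixels between the leaf circle and kinase label
#'   anchors.
#' @return A `layout_config` object.
#' @export
layout_config <- function(canvas_width = 1200, canvas_height = 1000,
                          tree_radius = 420, group_gap = 0.03,
                          start_angle = pi / 2,
                          level_radii = c(root = 0, group = 0.25,
                                          family = 0.55, subfamily = 0.8,
                                          kinase = 1),
                          atypical_panel = list(x = 960, y = 60, w = 220,
                                                h = 880, cell = 20),
                          label_offset = 8) {
  need <- c("root", "group", "family", "subfamily", "kinase")
  if (!all(need %in% names(level_radii))) {
    stop("level_radii must name levels ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lr <- as.numeric(level_radii[need])
  if (any(diff(lr) <= 0)) {
    stop("level_radii must be strictly increasing from root to kinase",
         call. = FALSE)
  }
  if (lr[1] != 0 || lr[5] != 1) {
    stop("level_radii must start at root = 0 and end at kinase = 1",
         call. = FALSE)
  }
  if (group_gap < 0) stop("group_gap must be >= 0", call. = FALSE)
  pn <- c("x", "y", "w", "h", "cell")
  if (!all(pn %in% names(atypical_panel))) {
    stop("atypical_panel must name ", paste(pn, collapse = ", "),
         call. = FALSE)
  }
  structure(list(canvas_width = as.numeric(canvas_width),
                 canvas_height = as.numeric(canvas_height),
                 tree_radius = as.numeric(tree_radius),
                 group_gap = as.numeric(group_gap),
                 start_angle = as.numeric(start_angle),
                 level_radii = stats::setNames(lr, need),
                 atypical_panel = lapply(atypical_panel[pn], as.numeric),
                 label_offset = as.numeric(label_offset)),
            class = "layout_config")
}

#' Build the classification hierarchy of the typical kinome
#'
#' Root, then typical groups in canonical order, then families
#' (alphabetical, case-insensitive), then subfamilies (alphabetical;
#' kinases with an empty subfamily attach directly to their family),
#' then kinases (alphabetical). Atypical records are excluded — they
#' are handled by the side panel.
#'
#' @param table A [kinome_table()].
#' @return A `hierarchy_node` (list with `label`, `level`, `children`,
#'   `leaf_count`).
#' @export
build_hierarchy <- function(table) {
  stopifnot(inherits(table, "kinome_table"))
  df <- as.data.frame(table)[table$group != "Atypical", , drop = FALSE]

  kinase_node <- function(xname) {
    list(label = xname, level = "kinase", children = list(), leaf_count = 1L)
  }
  internal_node <- function(label, level, children) {
    list(label = label, level = level, children = children,
         leaf_count = sum(vapply(children, `[[`, integer(1), "leaf_count")))
  }
  sort_ci <- function(x) x[order(tolower(x), method = "radix")]

  group_children <- list()
  for (g in typical_groups()) {
    gdf <- df[df$group == g, , drop = FALSE]
    if (nrow(gdf) == 0) next
    fam_children <- list()
    for (fam in sort_ci(unique(gdf$family))) {
      fdf <- gdf[gdf$family == fam, , drop = FALSE]
      direct <- fdf[fdf$subfamily == "", , drop = FALSE]
      subfams <- sort_ci(unique(fdf$subfamily[fdf$subfamily != ""]))
      children <- lapply(subfams, function(sf) {
        members <- sort_ci(fdf$xname[fdf$subfamily == sf])
        internal_node(sf, "subfamily", lapply(members, kinase_node))
      })
      children <- c(children,
                    lapply(sort_ci(direct$xname), kinase_node))
      fam_children[[length(fam_children) + 1L]] <-
        internal_node(fam, "family", children)
    }
    group_children[[length(group_children) + 1L]] <-
      internal_node(g, "group", fam_children)
  }
  internal_node("kinome", "root", group_children)
}

polar_xy <- function(cx, cy, r, theta) {
  c(x = cx + r * cos(theta), y = cy - r * sin(theta))
}

#' Compute the radial layout of the typical kinome tree
#'
#' The circle starting at `start_angle` is divided among the groups:
#' each group receives angular width proportional to its leaf count
#' after reserving one `group_gap` after each group. Within a group,
#' each child receives a contiguous sub-span proportional to its leaf
#' count, in hierarchy order. A node's anchor sits at the midpoint of
#' its span at its level's radius; leaves sit on the `tree_radius`
#' circle. Branch paths connect each parent anchor to each child anchor
#' through an elbow point at (child angle, parent radius). The result
#' is fully determined by the hierarchy and the configuration.
#'
#' @param root A [build_hierarchy()] node.
#' @param config A [layout_config()].
#' @return List with `leaf_positions` (data frame `xname`, `x`, `y`),
#'   `branch_paths` (list of 3 x 2 point matrices), `label_anchors`
#'   (data frame `xname`, `x`, `y`, `rotation` in degrees),
#'   `group_anchors` and `group_spans` (per-group `start`, `span`,
#'   `gap`), plus the canvas `center`.
#' @export
compute_radial_layout <- function(root, config) {
  stopifnot(inherits(config, "layout_config"))
  groups <- root$children
  n <- length(groups)
  if (n == 0) {
    return(list(leaf_positions = empty_positions(),
                branch_paths = list(),
                label_anchors = empty_anchors(),
                group_anchors = data.frame(label = character(0),
                                           x = numeric(0), y = numeric(0)),
                group_spans = data.frame(label = character(0),
                                         start = numeric(0),
                                         span = numeric(0),
                                         gap = numeric(0)),
                center = c(x = config$canvas_width / 2,
                           y = config$canvas_height / 2)))
  }
  total_gap <- n * config$group_gap
  if (total_gap >= 2 * pi) {
    stop("total group gaps must be smaller than the full circle",
         call. = FALSE)
  }
  avail <- 2 * pi - total_gap
  total_leaves <- root$leaf_count
  cx <- config$canvas_width / 2
  cy <- config$canvas_height / 2
  R <- config$tree_radius
  lr <- config$level_radii

  leaves <- list()
  labels <- list()
  paths <- list()

  place_node <- function(node, a0, a1, parent_anchor) {
    theta <- (a0 + a1) / 2
    r <- lr[[node$level]] * R
    anchor <- polar_xy(cx, cy, r, theta)
    if (!is.null(parent_anchor)) {
      elbow <- polar_xy(cx, cy, parent_anchor["r"], theta)
      paths[[length(paths) + 1L]] <<- matrix(
        c(parent_anchor["x"], parent_anchor["y"],
          elbow["x"], elbow["y"], anchor["x"], anchor["y"]),
        ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
    }
    if (node$level == "kinase") {
      leaves[[length(leaves) + 1L]] <<- list(xname = node$label,
                                             x = anchor[["x"]],
                                             y = anchor[["y"]])
      lab <- polar_xy(cx, cy, R + config$label_offset, theta)
      deg <- (-theta * 180 / pi) %% 360
      if (deg > 90 && deg < 270) deg <- deg + 180
      labels[[length(labels) + 1L]] <<- list(xname = node$label,
                                             x = lab[["x"]],
                                             y = lab[["y"]],
                                             rotation = deg %% 360)
      return(invisible(NULL))
    }
    a <- a0
    span <- a1 - a0
    for (child in node$children) {
      w <- span * child$leaf_count / node$leaf_count
      place_node(child, a, a + w,
                 c(anchor, r = stats::setNames(r, NULL)))
      a <- a + w
    }
  }

  spans <- data.frame(label = character(n), start = numeric(n),
                      span = numeric(n), gap = numeric(n),
                      stringsAsFactors = FALSE)
  ganchors <- data.frame(label = character(n), x = numeric(n),
                         y = numeric(n), stringsAsFactors = FALSE)
  a <- config$start_angle
  for (i in seq_len(n)) {
    g <- groups[[i]]
    w <- avail * g$leaf_count / total_leaves
    spans$label[i] <- g$label
    spans$start[i] <- a
    spans$span[i] <- w
    spans$gap[i] <- config$group_gap
    anchor <- polar_xy(cx, cy, lr[["group"]] * R, a + w / 2)
    ganchors$label[i] <- g$label
    ganchors$x[i] <- anchor[["x"]]
    ganchors$y[i] <- anchor[["y"]]
    root_anchor <- c(x = cx, y = cy, r = 0)
    place_node(g, a, a + w, root_anchor)
    a <- a + w + config$group_gap
  }

  list(
    leaf_positions = bind_rows_list(leaves, empty_positions()),
    branch_paths = paths,
    label_anchors = bind_rows_list(labels, empty_anchors()),
    group_anchors = ganchors,
    group_spans = spans,
    center = c(x = cx, y = cy)
  )
}

empty_positions <- function() {
  data.frame(xname = character(0), x = numeric(0), y = numeric(0),
             stringsAsFactors = FALSE)
}
empty_anchors <- function() {
  data.frame(xname = character(0), x = numeric(0), y = numeric(0),
             rotation = numeric(0), stringsAsFactors = FALSE)
}

bind_rows_list <- function(items, prototype) {
  if (length(items) == 0) return(prototype)
  cols <- stats::setNames(names(prototype), names(prototype))
  as.data.frame(lapply(cols, function(col) {
    if (is.character(prototype[[col]])) {
      vapply(items, function(it) as.character(it[[col]]), character(1))
    } else {
      vapply(items, function(it) as.numeric(it[[col]]), numeric(1))
    }
  }), stringsAsFactors = FALSE)
}

#' Lay out atypical kinases in the side panel
#'
#' Column-major grid inside the panel rectangle, grouped by family in
#' alphabetical order; each family contributes a header anchor followed
#' by its kinases (alphabetical). Vertical spacing is the grid cell
#' size; column width is five cells.
#'
#' @param table A [kinome_table()].
#' @param config A [layout_config()].
#' @return List with `leaf_positions` (data frame `xname`, `x`, `y`)
#'   and `family_anchors` (data frame `family`, `x`, `y`).
#' @export
place_atypical_panel <- function(table, config) {
  stopifnot(inherits(table, "kinome_table"),
            inherits(config, "layout_config"))
  panel <- config$atypical_panel
  df <- as.data.frame(table)[table$group == "Atypical", , drop = FALSE]
  fam_anchors <- data.frame(family = character(0), x = numeric(0),
                            y = numeric(0), stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    return(list(leaf_positions = empty_positions(),
                family_anchors = fam_anchors))
  }
  families <- unique(df$family)
  families <- families[order(tolower(families), method = "radix")]
  items <- list()  # (kind, name)
  for (fam in families) {
    items[[length(items) + 1L]] <- list(kind = "family", name = fam)
    members <- df$xname[df$family == fam]
    for (xn in members[order(tolower(members), method = "radix")]) {
      items[[length(items) + 1L]] <- list(kind = "kinase", name = xn)
    }
  }
  cell <- panel$cell
  col_width <- 5 * cell
  rows_per_col <- max(1L, floor(panel$h / cell))
  n_cols <- max(1L, floor(panel$w / col_width))
  if (length(items) > rows_per_col * n_cols) {
    stop(sprintf(paste0("atypical panel overflow: %d entries need more ",
                        "than %d x %d grid cells; enlarge the panel or ",
                        "reduce the cell size"),
                 length(items), rows_per_col, n_cols), call. = FALSE)
  }
  leaf <- list()
  for (i in seq_along(items)) {
    col <- (i - 1L) %/% rows_per_col
    row <- (i - 1L) %% rows_per_col
    x <- panel$x + col * col_width + cell / 2
    y <- panel$y + row * cell + cell / 2
    it <- items[[i]]
    if (it$kind == "family") {
      fam_anchors <- rbind(fam_anchors,
                           data.frame(family = it$name, x = x, y = y,
                                      stringsAsFactors = FALSE))
    } else {
      leaf[[length(leaf) + 1L]] <- list(xname = it$name, x = x, y = y)
    }
  }
  list(leaf_positions = bind_rows_list(leaf, empty_positions()),
       family_anchors = fam_anchors)
}

#' Compute the full kinome layout
#'
#' Combines [build_hierarchy()], [compute_radial_layout()] and
#' [place_atypical_panel()] into one layout holding positions for every
#' kinase in the table.
#'
#' @param table A [kinome_table()].
#' @param config A [layout_config()].
#' @param overrides Optional coordinate override table from
#'   [load_coordinate_table()]; listed kinases are moved to the given
#'   pixel positions, all others are untouched. Unknown names are
#'   reported in the `override_unknown` field.
#' @return A `kinome_layout` object.
#' @export
#' @examples
#' lay <- layout_kinome(load_kinome())
#' head(lay$leaf_positions)
layout_kinome <- function(table, config = layout_config(),
                          overrides = NULL) {
  root <- build_hierarchy(table)
  radial <- compute_radial_layout(root, config)
  panel <- place_atypical_panel(table, config)
  atypical_labels <- panel$leaf_positions
  if (nrow(atypical_labels) > 0) {
    atypical_labels$x <- atypical_labels$x + config$atypical_panel$cell / 2
    atypical_labels$rotation <- 0
  } else {
    atypical_labels <- empty_anchors()
  }
  leaf_positions <- rbind(radial$leaf_positions, panel$leaf_positions)
  label_anchors <- rbind(radial$label_anchors, atypical_labels)
  unknown <- character(0)
  if (!is.null(overrides) && nrow(overrides) > 0) {
    hit <- overrides$xname %in% leaf_positions$xname
    unknown <- overrides$xname[!hit]
    if (length(unknown) > 0) {
      warning("coordinate overrides for unknown kinase(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (i in which(hit)) {
      j <- match(overrides$xname[i], leaf_positions$xname)
      leaf_positions$x[j] <- overrides$x[i]
      leaf_positions$y[j] <- overrides$y[i]
    }
  }
  structure(list(leaf_positions = leaf_positions,
                 branch_paths = radial$branch_paths,
                 label_anchors = label_anchors,
                 group_anchors = radial$group_anchors,
                 group_spans = radial$group_spans,
                 family_anchors = panel$family_anchors,
                 center = radial$center,
                 config = config,
                 override_unknown = unknown),
            class = "kinome_layout")
}

#' Load a coordinate override table
#'
#' CSV with columns `xname`, `x`, `y`; permits pixel-faithful
#' reproduction of externally supplied layouts (e.g. classic poster
#' coordinates).
#'
#' @param path CSV file path.
#' @return Data frame with `xname`, `x`, `y`.
#' @export
load_coordinate_table <- function(path) {
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  need <- c("xname", "x", "y")
  if (!all(need %in% names(df))) {
    stop("coordinate table must have columns xname, x, y", call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(data.frame(xname = character(0), x = numeric(0), y = numeric(0),
                      stringsAsFactors = FALSE))
  }
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(x) | is.na(y) | !nzchar(df$xname))
  if (length(bad) > 0) {
    stop("malformed coordinate row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data.frame(xname = df$xname, x = x, y = y, stringsAsFactors = FALSE)
}

#' Serialize a layout deterministically
#'
#' Positions rounded to 3 decimal places; identical (table, config)
#' pairs produce byte-identical text across runs and platforms.
#'
#' @param layout A [layout_kinome()] result.
#' @return A single string.
#' @export
serialize_layout <- function(layout) {
  fmt <- function(v) sprintf("%.3f", round(v, 3))
  lp <- layout$leaf_positions
  lines <- c("leaf_positions",
             sprintf("%s\t%s\t%s", lp$xname, fmt(lp$x), fmt(lp$y)),
             "branch_paths",
             vapply(layout$branch_paths, function(p) {
               paste(sprintf("%s,%s", fmt(p[, "x"]), fmt(p[, "y"])),
                     collapse = ";")
             }, character(1)))
  paste0(paste(lines, collapse = "\n"), "\n")
}
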