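test_that("hierarchy mirrors the classification with correct leaf counts", {
  kin <- make_synthetic_kinome(2, 1, 1, seed = 0)
  root <- build_hierarchy(kin)
  expect_equal(length(root$children), 2)
  expect_equal(vapply(root$children, `[[`, integer(1), "leaf_count"),
               c(1L, 1L))

  kin <- load_kinome()
  root <- build_hierarchy(kin)
  expect_equal(length(root$children), 8)
  expect_equal(root$leaf_count, sum(kin$group != "Atypical"))
  # leaf_count consistency at every node
  check <- function(node) {
    if (node$level == "kinase") {
      expect_equal(node$leaf_count, 1L)
      return(1L)
    }
    total <- sum(vapply(node$children, check, integer(1)))
    expect_equal(node$leaf_count, total)
    total
  }
  check(root)
})

test_that("single kinase sits opposite the start angle", {
  kin <- make_synthetic_kinome(1, 1, 1, seed = 0)
  cfg <- layout_config(group_gap = 0, start_angle = 0)
  lay <- compute_radial_layout(build_hierarchy(kin), cfg)
  expect_equal(nrow(lay$leaf_positions), 1)
  # midpoint of [0, 2*pi] is pi: position (cx - R, cy)
  expect_equal(lay$leaf_positions$x, cfg$canvas_width / 2 - cfg$tree_radius)
  expect_equal(lay$leaf_positions$y, cfg$canvas_height / 2)
})

test_that("equal groups sit diametrically opposite; spans are proportional", {
  kin <- make_synthetic_kinome(2, 1, 1, seed = 0)
  cfg <- layout_config(group_gap = 0)
  lay <- compute_radial_layout(build_hierarchy(kin), cfg)
  mid <- lay$group_spans$start + lay$group_spans$span / 2
  expect_equal(abs(diff(mid)), pi)

  # leaf counts 1, 2, 1 -> spans pi/2, pi, pi/2
  df <- data.frame(
    xname = c("A1", "B1", "B2", "C1"),
    hgnc_symbol = "", uniprot_name = "", uniprot_ac = "",
    group = c("AGC", "CAMK", "CAMK", "CK1"),
    family = c("F1", "F2", "F2", "F3"),
    subfamily = "", stringsAsFactors = FALSE)
  df$aliases <- list(character(0), character(0), character(0), character(0))
  lay <- compute_radial_layout(build_hierarchy(kinome_table(df)), cfg)
  expect_equal(lay$group_spans$span, c(pi / 2, pi, pi / 2))
})

test_that("spans plus gaps close the full circle and angles are monotone", {
  for (seed in c(2, 13)) {
    kin <- make_synthetic_kinome(5, 3, 4, seed = seed)
    cfg <- layout_config(group_gap = 0.03)
    lay <- compute_radial_layout(build_hierarchy(kin), cfg)
    closure <- sum(lay$group_spans$span) + sum(lay$group_spans$gap)
    expect_lt(abs(closure - 2 * pi), 1e-9)
    expect_true(all(diff(lay$group_spans$start) > 0))
  }
  kin <- load_kinome()
  lay <- layout_kinome(kin)
  closure <- sum(lay$group_spans$span) + sum(lay$group_spans$gap)
  expect_lt(abs(closure - 2 * pi), 1e-9)
})

test_that("typical leaves lie on the tree-radius circle, atypical in the panel", {
  kin <- load_kinome()
  cfg <- layout_config()
  lay <- layout_kinome(kin, cfg)
  expect_setequal(lay$leaf_positions$xname, kin$xname)

  typical <- kin$xname[kin$group != "Atypical"]
  lp <- lay$leaf_positions
  r <- sqrt((lp$x - cfg$canvas_width / 2)^2 + (lp$y - cfg$canvas_height / 2)^2)
  expect_true(all(abs(r[lp$xname %in% typical] - cfg$tree_radius) < 1e-9))

  panel <- cfg$atypical_panel
  at <- lp[!lp$xname %in% typical, ]
  expect_true(all(at$x >= panel$x & at$x <= panel$x + panel$w))
  expect_true(all(at$y >= panel$y & at$y <= panel$y + panel$h))

  # no two leaves coincide
  expect_equal(anyDuplicated(round(lp$x, 6) + 1i * round(lp$y, 6)), 0)

  # 13 atypical family headers
  expect_equal(nrow(lay$family_anchors), 13)
})

test_that("atypical panel grid stacks members vertically by the cell size", {
  df <- data.frame(xname = c("AT1", "AT2", "AT3"),
                   hgnc_symbol = "", uniprot_name = "", uniprot_ac = "",
                   group = "Atypical", family = "PIKK", subfamily = "",
                   stringsAsFactors = FALSE)
  df$aliases <- list(character(0), character(0), character(0))
  kin <- kinome_table(df)
  res <- place_atypical_panel(kin, layout_config())
  expect_equal(nrow(res$leaf_positions), 3)
  expect_equal(diff(sort(res$leaf_positions$y)), c(20, 20))
  expect_equal(nrow(res$family_anchors), 1)

  tiny <- layout_config(atypical_panel = list(x = 0, y = 0, w = 100,
                                              h = 40, cell = 20))
  expect_error(place_atypical_panel(kin, tiny), "overflow")

  typ <- make_synthetic_kinome(1, 1, 1, seed = 0)  # group AGC, no atypicals
  empty <- place_atypical_panel(typ, layout_config())
  expect_equal(nrow(empty$leaf_positions), 0)
})

test_that("layout is deterministic and scales with tree_radius", {
  kin <- make_synthetic_kinome(4, 2, 3, seed = 1)
  cfg1 <- layout_config(tree_radius = 200)
  cfg2 <- layout_config(tree_radius = 400)
  l1a <- layout_kinome(kin, cfg1)
  l1b <- layout_kinome(kin, cfg1)
  expect_identical(serialize_layout(l1a), serialize_layout(l1b))

  l2 <- layout_kinome(kin, cfg2)
  cx <- cfg1$canvas_width / 2; cy <- cfg1$canvas_height / 2
  typical <- kin$xname[kin$group != "Atypical"]
  p1 <- l1a$leaf_positions[l1a$leaf_positions$xname %in% typical, ]
  p2 <- l2$leaf_positions[match(p1$xname, l2$leaf_positions$xname), ]
  d1 <- sqrt((p1$x - cx)^2 + (p1$y - cy)^2)
  d2 <- sqrt((p2$x - cx)^2 + (p2$y - cy)^2)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("coordinate overrides move only the listed kinases", {
  kin <- fixture_kinome()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("xname,x,y\nEGFR,100,200\n", path)
  ov <- load_coordinate_table(path)
  lay0 <- layout_kinome(kin)
  lay1 <- layout_kinome(kin, overrides = ov)
  moved <- lay1$leaf_positions[lay1$leaf_positions$xname == "EGFR", ]
  expect_equal(c(moved$x, moved$y), c(100, 200))
  rest0 <- lay0$leaf_positions[lay0$leaf_positions$xname != "EGFR", ]
  rest1 <- lay1$leaf_positions[lay1$leaf_positions$xname != "EGFR", ]
  expect_identical(rest0, rest1)

  writeLines("xname,x,y\nNOPE,1,2\n", path)
  expect_warning(lay2 <- layout_kinome(kin, overrides = load_coordinate_table(path)),
                 "NOPE")
  expect_equal(lay2$override_unknown, "NOPE")
  expect_identical(lay2$leaf_positions, lay0$leaf_positions)

  writeLines("xname,x,y\n", path)
  expect_equal(nrow(load_coordinate_table(path)), 0)
  writeLines("xname,x,y\nEGFR,abc,2\n", path)
  expect_error(load_coordinate_table(path), "malformed")
})

test_that("config invariants are enforced", {
  expect_error(layout_config(level_radii = c(root = 0, group = 0.5,
                                             family = 0.4, subfamily = 0.8,
                                             kinase = 1)),
               "increasing")
  expect_error(layout_config(group_gap = -1), "group_gap")
  kin <- make_synthetic_kinome(8, 1, 1, seed = 0)
  big_gap <- layout_config(group_gap = 1)
  expect_error(compute_radial_layout(build_hierarchy(kin), big_gap),
               "gaps")
})
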