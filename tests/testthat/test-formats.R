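test_that("minimal text applies directives to succeeding kinases", {
  doc <- paste(
    "# cardiomyopathy panel",
    "@ shape=square size=25x25 fill=red stroke=grey",
    "EGFR", "ABL1", "ABL2",
    "@ shape=circle size=10x10 fill=blue",
    "EGFR", "ABL1",
    sep = "\n")
  p <- parse_minimal_text(doc)
  expect_equal(length(p$set), 5)
  shapes <- vapply(p$set$annotations, function(a) a$style$shape, character(1))
  expect_equal(shapes, c("square", "square", "square", "circle", "circle"))
  expect_equal(p$set$annotations[[1]]$style$width, 25)
  expect_equal(p$set$annotations[[1]]$style$stroke, "#BEBEBE")
  expect_equal(p$set$annotations[[4]]$style$fill, "#0000FF")
  expect_equal(nrow(p$unresolved), 0)
})

test_that("minimal text resolves names and reports the unresolved", {
  idx <- build_name_index(fixture_kinome())
  doc <- "erbb1\nABL\nnosuchkinase\nkin9\n"
  p <- parse_minimal_text(doc, idx)
  got <- vapply(p$set$annotations, `[[`, character(1), "xname")
  expect_equal(got, c("EGFR", "KIN9"))
  expect_equal(p$unresolved$name, c("ABL", "nosuchkinase"))
  expect_equal(p$unresolved$reason, c("ambiguous", "unmatched"))
  # nothing silently dropped
  expect_equal(length(p$set) + nrow(p$unresolved), 4)
})

test_that("minimal text parse errors carry line numbers", {
  expect_error(parse_minimal_text("@ shape"), "line 1")
  expect_error(parse_minimal_text("EGFR\n@ size=25"), "line 2")
  expect_error(parse_minimal_text("@ color=red"), "unknown style key")
  expect_error(parse_minimal_text("@ shape=hexagon"), "unknown shape")
})

test_that("minimal text writer emits one directive per style run", {
  a <- annotation_style("circle", 10, 10, fill = "#112233")
  b <- annotation_style("square", 20, 20, fill = "#445566")
  mk <- function(sty, xn) annotation(xn, sty)
  set <- annotation_set(list(mk(a, "K1"), mk(b, "K2"), mk(a, "K3"),
                             mk(b, "K4"), mk(a, "K5")))
  txt <- write_minimal_text(set)
  expect_equal(sum(grepl("^@", strsplit(txt, "\n")[[1]])), 5)

  runs <- annotation_set(list(mk(a, "K1"), mk(a, "K2"), mk(b, "K3")))
  expect_equal(sum(grepl("^@", strsplit(write_minimal_text(runs), "\n")[[1]])), 2)
  expect_equal(write_minimal_text(annotation_set()), "")
  expect_equal(length(parse_minimal_text("")$set), 0)
})

test_that("CSV carries defaults, values and extra info columns", {
  set <- parse_annotation_csv("xname\nEGFR\nABL1\nSRC\n")
  expect_equal(length(set), 3)
  expect_identical(set$annotations[[1]]$style, default_style())

  set <- parse_annotation_csv(
    "xname,value,unit,\"Kd(nM)\"\nEGFR,12.5,nM,40\n")
  ann <- set$annotations[[1]]
  expect_equal(ann$value, 12.5)
  expect_equal(ann$unit, "nM")
  expect_equal(ann$info, c("Kd(nM)" = "40"))

  expect_equal(length(parse_annotation_csv("xname,shape\n")), 0)
  expect_error(parse_annotation_csv("shape\ncircle\n"), "xname")
  expect_error(parse_annotation_csv("xname,value\nEGFR,abc\n"),
               "row 1")
})

test_that("serializer round trips are identities on random sets", {
  withr::with_seed(123, {
    for (rep in 1:100) {
      set <- rand_annotation_set(sample(0:6, 1))

      expect_identical(parse_annotation_csv(write_annotation_csv(set)), set)
      expect_identical(parse_annotation_xml(write_annotation_xml(set)), set)

      st <- rand_map_state(sample(0:4, 1))
      expect_identical(parse_kmap(write_kmap(st)), st)

      lossy <- strip_payload(set)
      expect_identical(parse_minimal_text(write_minimal_text(lossy))$set,
                       lossy)
    }
  })
})

test_that("minimal text is documented-lossy: info and values drop", {
  ann <- annotation("EGFR", default_style(), value = 3.5, unit = "nM",
                    info = c(assay = "KdELECT"))
  set <- annotation_set(list(ann), provenance = "panel")
  back <- parse_minimal_text(write_minimal_text(set))$set
  expect_identical(back, strip_payload(set))
  expect_false(identical(back, set))
})

test_that("XML and KMAP preserve per-annotation info order", {
  a1 <- annotation("EGFR", info = c(z = "1", a = "2"))
  a2 <- annotation("ABL1", info = c(a = "2", z = "1"))
  set <- annotation_set(list(a1, a2))
  expect_identical(parse_annotation_xml(write_annotation_xml(set)), set)
  st <- map_state(set)
  expect_identical(parse_kmap(write_kmap(st)), st)
})

test_that("XML export is well-formed with one element per annotation", {
  set <- rand_annotation_set(3)
  doc <- xml2::read_xml(write_annotation_xml(set))
  expect_equal(xml2::xml_name(doc), "annotation_set")
  expect_equal(length(xml2::xml_find_all(doc, "./annotation")), 3)
  empty <- xml2::read_xml(write_annotation_xml(annotation_set()))
  expect_equal(length(xml2::xml_children(empty)), 0)
})

test_that("KMAP schema is strict and versioned", {
  st <- map_state(annotation_set(list(annotation("EGFR"))))
  km <- write_kmap(st)
  expect_identical(parse_kmap(km), st)

  bad_zoom <- sub('"zoom": 1', '"zoom": 0', km)
  expect_error(parse_kmap(bad_zoom), "zoom")

  bad_version <- sub('"schema_version": 1', '"schema_version": 99', km)
  expect_error(parse_kmap(bad_version), "unsupported")

  unknown <- sub('"zoom": 1', '"zoom": 1,\n  "surprise": true', km)
  expect_error(parse_kmap(unknown), "unknown KMAP field")

  bad_flag <- sub('"branches"', '"sprinkles"', km)
  expect_error(parse_kmap(bad_flag), "visible component")

  expect_error(parse_kmap("{not json"), "invalid KMAP")
})
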