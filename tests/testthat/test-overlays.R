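test_that("association filter pins the score boundary and evidence whitelist", {
  recs <- disease_associations(
    xname = c("EGFR", "ABL1", "SRC", "KIT", "BRAF"),
    disease = paste0("d", 1:5),
    therapeutic_area = "oncology",
    score = c(0.05, 0.1, 0.5, 0.1, 0.09),
    evidence_types = list("genetic", "literature", c("drug", "literature"),
                          "somatic_mutation", c("drug", "genetic")))
  kept <- filter_associations(recs)
  # score 0.05 excluded; literature-only excluded; boundary 0.1 kept;
  # {drug, literature} at 0.5 kept
  expect_equal(kept$xname, c("SRC", "KIT"))
  # idempotent
  expect_identical(filter_associations(kept), kept)
  # order preserved, input untouched
  expect_equal(nrow(recs), 5)
})

test_that("evidence spellings from upstream dumps are canonicalized", {
  recs <- disease_associations("EGFR", "d", "a", 0.5,
                               list(c("somatic mutations", "Drugs")))
  expect_setequal(recs$evidence_types[[1]], c("somatic_mutation", "drug"))
  expect_error(disease_associations("EGFR", "d", "a", 0.5,
                                    list("hearsay")), "unknown evidence")
  expect_error(disease_associations("EGFR", "d", "a", 1.5, list("drug")),
               "scores")
  expect_error(disease_associations("EGFR", "d", "a", 0.5, list(character(0))),
               "non-empty")
})

test_that("filter agrees with the brute-force oracle on 10000 records", {
  kin <- load_kinome()
  ov <- make_synthetic_overlays(kin, n_diseases = 221, seed = 17)
  recs <- ov$associations
  expect_gt(nrow(recs), 9000)
  recs <- recs[seq_len(min(nrow(recs), 10000)), , drop = FALSE]
  kept <- filter_associations(recs)
  expect_identical(kept$xname, recs$xname[oracle_filter(recs)])
  expect_identical(kept$score, recs$score[oracle_filter(recs)])
})

test_that("synthetic overlays are deterministic with the stated margins", {
  kin <- make_synthetic_kinome(4, 3, 4, seed = 2)
  a <- make_synthetic_overlays(kin, n_diseases = 5, seed = 3)
  b <- make_synthetic_overlays(kin, n_diseases = 5, seed = 3)
  expect_identical(a, b)
  expect_error(make_synthetic_overlays(kin, n_diseases = 0), "n_diseases")

  one <- make_synthetic_kinome(1, 1, 1, seed = 0)
  tiny <- make_synthetic_overlays(one, n_diseases = 1, seed = 0)
  expect_lte(nrow(tiny$associations), 1)

  # kept fraction ~ 0.9 (score clause) x 0.7 (evidence clause)
  kin <- load_kinome()
  ov <- make_synthetic_overlays(kin, n_diseases = 221, seed = 29)
  n <- nrow(ov$associations)
  kept <- nrow(filter_associations(ov$associations))
  p <- 0.9 * 0.7
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(kept / n - p), 3 * se)

  # about 40% of structure counts are exact zeros
  s <- ov$overlays[ov$overlays$metric_name == "n_structures", ]
  zero_frac <- mean(s$value == 0)
  expect_lt(abs(zero_frac - 0.4), 3 * sqrt(0.4 * 0.6 / nrow(s)))
})

test_that("overlay records convert to annotations with tooltip payloads", {
  empty <- overlay_to_annotations(overlay_records(character(0), character(0),
                                                  character(0), numeric(0)))
  expect_equal(length(empty$set), 0)

  recs <- overlay_records(c("EGFR", "ABL1", "SRC"), "chembl_activities",
                          "n_activities", c(1, 10, 100))
  conv <- overlay_to_annotations(recs, scale = size_scale(10, 30, "log10"))
  sizes <- vapply(conv$set$annotations, function(a) a$style$width, numeric(1))
  expect_equal(sizes, c(10, 20, 30))
  expect_equal(conv$set$annotations[[1]]$info[["source"]],
               "chembl_activities")

  assoc <- disease_associations("EGFR", "non-small cell lung carcinoma",
                                "oncology", 0.8,
                                list(c("genetic", "drug")))
  conv <- overlay_to_annotations(assoc)
  info <- conv$set$annotations[[1]]$info
  expect_setequal(names(info),
                  c("disease", "therapeutic_area", "score", "evidence_types"))
  expect_equal(info[["evidence_types"]], "genetic|drug")
  expect_equal(conv$set$annotations[[1]]$value, 0.8)
})

test_that("unresolvable overlay kinases are reported, counts conserved", {
  idx <- build_name_index(fixture_kinome())
  recs <- overlay_records(c("erbb1", "ABL", "nosuch"), "custom", "m",
                          c(1, 2, 3))
  conv <- overlay_to_annotations(recs, index = idx)
  expect_equal(length(conv$set), 1)
  expect_equal(conv$set$annotations[[1]]$xname, "EGFR")
  expect_equal(conv$unresolved$xname, c("ABL", "nosuch"))
  expect_equal(length(conv$set) + nrow(conv$unresolved), nrow(recs))
})

test_that("overlay and disease CSV readers validate their schemas", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("xname,source,metric_name,value\nEGFR,pdb_structures,n,5\n", p)
  recs <- read_overlay_csv(p)
  expect_equal(recs$value, 5)
  writeLines("xname,source,metric_name,value\nEGFR,pdb_structures,n,abc\n", p)
  expect_error(read_overlay_csv(p), "row")
  writeLines("xname,value\nEGFR,5\n", p)
  expect_error(read_overlay_csv(p), "columns")

  writeLines(paste0("xname,disease,therapeutic_area,score,evidence_types\n",
                    "EGFR,lung carcinoma,oncology,0.92,genetic|drugs\n"), p)
  d <- read_disease_csv(p)
  expect_equal(d$evidence_types[[1]], c("genetic", "drug"))
  expect_equal(d$score, 0.92)
})
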