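# Per-kinase overlay tables: quantitative metrics (structure counts,
# activity counts, profiling values) and scored disease associations
# with evidence types, plus the score/evidence filter applied to
# precompiled association sources and a synthetic fixture generator
# emulating them.

OVERLAY_SOURCES <- c("pdb_structures", "chembl_activities", "profiling",
                     "custom")
EVIDENCE_TYPES <- c("genetic", "somatic_mutation", "drug",
                    "affected_pathway", "rna_expression", "literature",
                    "animal_model", "other")
EVIDENCE_WHITELIST <- c("genetic", "somatic_mutation", "drug",
                        "affected_pathway", "rna_expression")

# Upstream dumps name evidence types inconsistently; accept common
# spellings and map them onto the singular snake_case tokens.
EVIDENCE_ALIASES <- c(
  "genetic" = "genetic", "genetic_association" = "genetic",
  "somatic_mutation" = "somatic_mutation", "somatic_mutations" = "somatic_mutation",
  "somatic mutation" = "somatic_mutation", "somatic mutations" = "somatic_mutation",
  "drug" = "drug", "drugs" = "drug", "known_drug" = "drug",
  "affected_pathway" = "affected_pathway", "affected_pathways" = "affected_pathway",
  "affected pathway" = "affected_pathway", "affected pathways" = "affected_pathway",
  "rna_expression" = "rna_expression", "rna expression" = "rna_expression",
  "literature" = "literature", "text_mining" = "literature",
  "animal_model" = "animal_model", "animal_models" = "animal_model",
  "other" = "other")

canonical_evidence <- function(x) {
  x <- tolower(trimws(x))
  mapped <- unname(EVIDENCE_ALIASES[x])
  bad <- x[is.na(mapped)]
  if (length(bad) > 0) {
    stop("unknown evidence type(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  unique(mapped)
}

#' Construct a disease-association table
#'
#' @param xname,disease,therapeutic_area Character vectors.
#' @param score Numeric in `[0, 1]`.
#' @param evidence_types List of character vectors (non-empty subsets
#'   of the evidence vocabulary; common alternate spellings accepted).
#' @return Data frame with class `disease_associations`.
#' @export
disease_associations <- function(xname, disease, therapeutic_area,
                                 score, evidence_types) {
  score <- as.numeric(score)
  if (any(!is.finite(score)) || any(score < 0 | score > 1)) {
    stop("association scores must lie in [0, 1]", call. = FALSE)
  }
  if (!is.list(evidence_types)) evidence_types <- list(evidence_types)
  ev <- lapply(evidence_types, canonical_evidence)
  if (any(lengths(ev) == 0)) {
    stop("evidence_types must be non-empty on ingest", call. = FALSE)
  }
  df <- data.frame(xname = as.character(xname),
                   disease = as.character(disease),
                   therapeutic_area = as.character(therapeutic_area),
                   score = score, stringsAsFactors = FALSE)
  df$evidence_types <- ev
  class(df) <- c("disease_associations", "data.frame")
  df
}

#' Filter disease associations by score and evidence type
#'
#' Keeps exactly the records with score >= 0.1 whose evidence types
#' intersect the whitelist (genetic, somatic mutation, drug, affected
#' pathway, RNA expression); entries with low scores (< 0.1) or
#' supported only by other evidence (e.g. literature mining alone) are
#' excluded. Input order is preserved; the input is not modified. The
#' filter is idempotent.
#'
#' @param records A [disease_associations()] table.
#' @param min_score Score threshold; records with `score < min_score`
#'   are excluded (so the boundary value itself is kept).
#' @param whitelist Evidence types that qualify a record.
#' @return The filtered [disease_associations()] table.
#' @export
filter_associations <- function(records, min_score = 0.1,
                                whitelist = EVIDENCE_WHITELIST) {
  stopifnot(inherits(records, "disease_associations"))
  if (any(records$score < 0 | records$score > 1)) {
    stop("association scores must lie in [0, 1]", call. = FALSE)
  }
  keep <- records$score >= min_score &
    vapply(records$evidence_types,
           function(ev) length(intersect(ev, whitelist)) > 0, logical(1))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(records)
  out
}

#' Construct a per-kinase overlay metric table
#'
#' @param xname Kinase identifiers.
#' @param source One of `"pdb_structures"`, `"chembl_activities"`,
#'   `"profiling"`, `"custom"`.
#' @param metric_name Metric label, e.g. `"n_structures"`.
#' @param value Non-negative finite numbers.
#' @return Data frame with class `overlay_records`.
#' @export
overlay_records <- function(xname, source, metric_name, value) {
  source <- as.character(source)
  bad <- setdiff(unique(source), OVERLAY_SOURCES)
  if (length(bad) > 0) {
    stop("unknown overlay source(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  value <- as.numeric(value)
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("overlay values must be finite and >= 0", call. = FALSE)
  }
  df <- data.frame(xname = as.character(xname), source = source,
                   metric_name = as.character(metric_name), value = value,
                   stringsAsFactors = FALSE)
  class(df) <- c("overlay_records", "data.frame")
  df
}

#' Convert overlay or disease records to annotations
#'
#' One annotation per record: the metric value (or association score)
#' becomes the annotation value, and source/metric (or
#' disease/therapeutic area/score/evidence) fields populate `info` for
#' tooltips. Records whose kinase does not resolve uniquely against the
#' index are collected in the unresolved report, never silently
#' dropped.
#'
#' @param records An [overlay_records()] or [disease_associations()]
#'   table.
#' @param style Base [annotation_style()] for every marker.
#' @param scale Optional [size_scale()]; when given, marker sizes are
#'   rescaled from the values via [rescale_sizes()].
#' @param index Optional [build_name_index()] used to resolve `xname`.
#' @return List with `set` (an [annotation_set()]) and `unresolved`
#'   (data frame `xname`, `reason`).
#' @export
overlay_to_annotations <- function(records, style = default_style(),
                                   scale = NULL, index = NULL) {
  is_disease <- inherits(records, "disease_associations")
  if (!is_disease && !inherits(records, "overlay_records")) {
    stop("records must be overlay_records or disease_associations",
         call. = FALSE)
  }
  anns <- list()
  unres <- list()
  for (i in seq_len(nrow(records))) {
    xn <- records$xname[i]
    if (!is.null(index)) {
      res <- resolve_name(xn, index)
      if (res$status != "unique") {
        unres[[length(unres) + 1L]] <- list(xname = xn,
                                            reason = res$status)
        next
      }
      xn <- res$match
    }
    if (is_disease) {
      info <- c(disease = records$disease[i],
                therapeutic_area = records$therapeutic_area[i],
                score = num_fmt(records$score[i]),
                evidence_types = paste(records$evidence_types[[i]],
                                       collapse = "|"))
      value <- records$score[i]
      unit <- "score"
    } else {
      info <- c(source = records$source[i],
                metric = records$metric_name[i])
      value <- records$value[i]
      unit <- records$metric_name[i]
    }
    anns[[length(anns) + 1L]] <- annotation(xn, style, value = value,
                                            unit = unit, info = info)
  }
  set <- annotation_set(anns, provenance = if (is_disease) {
    "disease associations"
  } else "overlay metrics")
  if (!is.null(scale)) set <- rescale_sizes(set, scale)
  report <- if (length(unres) == 0) {
    data.frame(xname = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(xname = vapply(unres, `[[`, character(1), "xname"),
               reason = vapply(unres, `[[`, character(1), "reason"),
               stringsAsFactors = FALSE)
  }
  list(set = set, unresolved = report)
}

#' Generate synthetic overlay fixtures
#'
#' Emulates the precompiled data sources at desk scale, deterministic
#' per seed. Per kinase: a structure count from a zero-inflated
#' discrete distribution (about 40% exact zeros, matching the large
#' fraction of kinases without experimental structures) and an activity
#' count log-uniform in `[1, 10000]`. Per (kinase, disease) pair, with
#' inclusion probability 0.1: a score uniform in `[0, 1]` and evidence
#' types that are, with probability 0.3, literature only, and otherwise
#' a random non-empty subset of the whitelisted types (plus occasional
#' non-whitelisted extras) — so the evidence clause of
#' [filter_associations()] passes with probability exactly 0.7.
#'
#' @param table A [kinome_table()].
#' @param n_diseases Number of synthetic diseases (>= 1).
#' @param seed Integer seed.
#' @return List with `overlays` (an [overlay_records()] table with
#'   structure and activity counts) and `associations` (a
#'   [disease_associations()] table).
#' @export
make_synthetic_overlays <- function(table, n_diseases = 10, seed = 0L) {
  stopifnot(inherits(table, "kinome_table"))
  if (!is.finite(n_diseases) || n_diseases < 1) {
    stop("n_diseases must be >= 1", call. = FALSE)
  }
  n_diseases <- as.integer(n_diseases)
  xnames <- table$xname
  n <- length(xnames)
  with_seed(seed, {
    zero <- stats::runif(n) < 0.4
    structures <- ifelse(zero, 0, 1 + stats::rpois(n, lambda = 8))
    activities <- round(10 ^ stats::runif(n, 0, 4))
    overlays <- overlay_records(
      xname = c(xnames, xnames),
      source = rep(c("pdb_structures", "chembl_activities"), each = n),
      metric_name = rep(c("n_structures", "n_activities"), each = n),
      value = c(structures, activities))

    areas <- sprintf("area%02d", ((seq_len(n_diseases) - 1L) %% 16L) + 1L)
    ax <- character(0); ad <- character(0); aa <- character(0)
    as_ <- numeric(0); ae <- list()
    for (d in seq_len(n_diseases)) {
      inc <- stats::runif(n) < 0.1
      for (i in which(inc)) {
        ax <- c(ax, xnames[i])
        ad <- c(ad, sprintf("disease%03d", d))
        aa <- c(aa, areas[d])
        as_ <- c(as_, stats::runif(1))
        ev <- if (stats::runif(1) < 0.3) {
          "literature"
        } else {
          k <- sample(length(EVIDENCE_WHITELIST), 1)
          picked <- sample(EVIDENCE_WHITELIST, k)
          extras <- setdiff(EVIDENCE_TYPES, EVIDENCE_WHITELIST)
          picked <- c(picked, extras[stats::runif(length(extras)) < 0.2])
          picked
        }
        ae[[length(ae) + 1L]] <- ev
      }
    }
    associations <- if (length(ax) == 0) {
      empty <- disease_associations("x", "d", "a", 0.5, list("genetic"))
      empty[0, , drop = FALSE]
    } else {
      disease_associations(ax, ad, aa, as_, ae)
    }
    list(overlays = overlays, associations = associations)
  })
}

#' Read an overlay metric CSV
#'
#' Columns: `xname`, `source`, `metric_name`, `value`.
#'
#' @param path CSV file path.
#' @return An [overlay_records()] table.
#' @export
read_overlay_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  need <- c("xname", "source", "metric_name", "value")
  if (!all(need %in% names(df))) {
    stop("overlay CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(value))
  if (length(bad) > 0) {
    stop("non-numeric overlay value in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  overlay_records(df$xname, df$source, df$metric_name, value)
}

#' Read a disease-association CSV
#'
#' Columns: `xname`, `disease`, `therapeutic_area`, `score`,
#' `evidence_types` (`|`-separated).
#'
#' @param path CSV file path.
#' @return A [disease_associations()] table.
#' @export
read_disease_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  need <- c("xname", "disease", "therapeutic_area", "score",
            "evidence_types")
  if (!all(need %in% names(df))) {
    stop("disease CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score))
  if (length(bad) > 0) {
    stop("non-numeric score in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ev <- lapply(strsplit(df$evidence_types, "|", fixed = TRUE), trimws)
  disease_associations(df$xname, df$disease, df$therapeutic_area, score, ev)
}
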