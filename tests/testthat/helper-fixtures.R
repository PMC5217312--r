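# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately avoid the package's internal code paths: the
# Levenshtein DP, the normalizer and the ranking below are written
# from the contract, not shared with the implementation.

# --- tiny hand-built kinome fixtures ------------------------------------

fixture_kinome <- function() {
  df <- data.frame(
    xname = c("EGFR", "ABL1", "ABL2", "KIN9"),
    hgnc_symbol = c("EGFR", "ABL1", "ABL2", ""),
    uniprot_name = c("Epidermal growth factor receptor", "", "", ""),
    uniprot_ac = c("P00533", "P00519", "", ""),
    group = c("TK", "TK", "TK", "Atypical"),
    family = c("EGFR", "Abl", "Abl", "PIKK"),
    subfamily = c("", "", "", ""),
    stringsAsFactors = FALSE
  )
  df$aliases <- list(c("ErbB1", "HER1"), c("ABL", "c-Abl"), c("ABL", "ARG"),
                     character(0))
  kinome_table(df, source_tag = "fixture")
}

# --- random annotation fixtures (seeded by the caller) ------------------

rand_color <- function() {
  sprintf("#%02X%02X%02X", sample(0:255, 1), sample(0:255, 1),
          sample(0:255, 1))
}

rand_style <- function() {
  annotation_style(
    shape = sample(c("circle", "square", "triangle", "diamond", "star"), 1),
    width = round(runif(1, 1, 60), 2),
    height = round(runif(1, 1, 60), 2),
    fill = rand_color(),
    stroke = if (runif(1) < 0.3) "none" else rand_color(),
    stroke_width = round(runif(1, 0, 4), 2),
    opacity = round(runif(1), 2),
    label = sample(c("", "hit", "panel A", "IC50<100nM"), 1)
  )
}

rand_annotation <- function(xnames) {
  # keys drawn in a fixed pool order: a columnar serialization (CSV)
  # carries one global info-column order, so fixtures use a consistent
  # per-annotation key order; scrambled orders are covered by the
  # dedicated XML/KMAP order-preservation test
  pool <- c("Kd(nM)", "assay", "note", "src")
  keep <- pool[sort(sample(4, sample(0:3, 1)))]
  info <- character(0)
  for (key in keep) {
    info[[key]] <- paste(sample(c(letters, "0", "5", " "), 6, TRUE),
                         collapse = "")
  }
  annotation(sample(xnames, 1), rand_style(),
             value = if (runif(1) < 0.5) NA_real_
                     else round(runif(1, 0.001, 5000), 3),
             unit = sample(c("", "nM", "uM", "count"), 1),
             info = info)
}

rand_annotation_set <- function(n, xnames = c("EGFR", "ABL1", "SRC",
                                              "BRAF", "KIT")) {
  annotation_set(lapply(seq_len(n), function(i) rand_annotation(xnames)),
                 provenance = sample(c("", "test run", "profiling panel"), 1))
}

rand_map_state <- function(n = 4) {
  vis <- sample(c("branches", "group_labels", "kinase_labels", "legend",
                  "atypical_panel"), sample(0:5, 1))
  map_state(rand_annotation_set(n),
            label_font = list(name = sample(c("sans-serif", "Helvetica"), 1),
                              size = sample(6:14, 1)),
            zoom = round(runif(1, 0.25, 4), 2),
            visible_components = vis,
            interactive = runif(1) < 0.5)
}

# strip the fields the minimal text format does not carry
strip_payload <- function(set) {
  set$annotations <- lapply(set$annotations, function(a) {
    a$value <- NA_real_
    a$unit <- ""
    a$info <- character(0)
    a
  })
  set$provenance <- ""
  set
}

# --- independent oracles -------------------------------------------------

oracle_levenshtein <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0) return(nb)
  if (nb == 0) return(na)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- numeric(nb + 1)
    cur[1] <- i
    for (j in seq_len(nb)) {
      cost <- if (av[i] == bv[j]) 0 else 1
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1, prev[j] + cost)
    }
    prev <- cur
  }
  prev[nb + 1]
}

oracle_normalize <- function(x) {
  x <- tolower(sub("^\\s+", "", sub("\\s+$", "", x)))
  chars <- strsplit(x, "")[[1]]
  paste(chars[!chars %in% c(" ", "-", "_", ".", "/", "(", ")")],
        collapse = "")
}

# Brute-force suggestion ranking: score every indexed (key, xname,
# scheme) triple with the contract's tuple and sort.
oracle_suggest <- function(query, table, limit = 10L) {
  q <- oracle_normalize(query)
  scheme_rank <- c(manning = 1, hgnc = 2, uniprot = 3, alias = 4)
  class_rank <- c(exact = 1, prefix = 2, substring = 3, fuzzy = 4)
  rows <- list()
  emit <- function(raw, scheme, owner) {
    if (is.na(raw) || !nzchar(raw)) return()
    key <- oracle_normalize(raw)
    if (!nzchar(key)) return()
    d <- oracle_levenshtein(q, key)
    cls <- if (key == q) "exact"
      else if (substr(key, 1, nchar(q)) == q) "prefix"
      else if (grepl(q, key, fixed = TRUE)) "substring"
      else if (nchar(q) >= 4 && d <= 2) "fuzzy"
      else NA_character_
    if (is.na(cls)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      xname = owner, scheme = scheme, match_class = cls,
      edit_distance = as.integer(d), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(table))) {
    emit(table$xname[i], "manning", table$xname[i])
    emit(table$hgnc_symbol[i], "hgnc", table$xname[i])
    emit(table$uniprot_name[i], "uniprot", table$xname[i])
    for (al in table$aliases[[i]]) emit(al, "alias", table$xname[i])
  }
  empty <- data.frame(xname = character(0), scheme = character(0),
                      match_class = character(0),
                      edit_distance = integer(0), stringsAsFactors = FALSE)
  if (length(rows) == 0 || !nzchar(q)) return(empty)
  df <- do.call(rbind, rows)
  df <- unique(df)
  df <- df[order(class_rank[df$match_class], scheme_rank[df$scheme],
                 df$edit_distance, df$xname, method = "radix"), ,
           drop = FALSE]
  df <- df[!duplicated(df$xname), , drop = FALSE]
  df <- df[seq_len(min(nrow(df), limit)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Brute-force association filter: plain per-record two-clause check.
oracle_filter <- function(records) {
  ok <- c("genetic", "somatic_mutation", "drug", "affected_pathway",
          "rna_expression")
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    keep[i] <- records$score[i] >= 0.1 &&
      any(records$evidence_types[[i]] %in% ok)
  }
  keep
}

count_markers <- function(svg) {
  doc <- xml2::read_xml(svg)
  grp <- xml2::xml_find_all(doc, "//*[local-name()='g'][@class='markers']")
  if (length(grp) == 0) return(0L)
  direct <- xml2::xml_find_all(
    grp[[1]], "./*[local-name()!='text' and local-name()!='g']")
  wrapped <- xml2::xml_find_all(
    grp[[1]], "./*[local-name()='g']/*[local-name()!='title']")
  length(direct) + length(wrapped)
}
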