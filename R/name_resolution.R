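# Name resolution: link user-supplied kinase names in any supported
# nomenclature scheme (Manning display name, HGNC symbol, UniProt
# recommended name, aliases) to records of a kinome table, with ranked
# suggestions for incomplete or ambiguous queries.

SCHEME_ORDER <- c("manning", "hgnc", "uniprot", "alias")
MATCH_CLASS_ORDER <- c("exact", "prefix", "substring", "fuzzy")

#' Normalize a kinase name for matching
#'
#' Case-folds to lower case, strips leading/trailing whitespace and
#' removes spaces, hyphens, underscores, dots, slashes and parentheses.
#' Idempotent. Greek letters are not transliterated; alias tables carry
#' spelled-out variants instead.
#'
#' @param raw Character vector of raw names.
#' @return Character vector of normalized names (empty in, empty out).
#' @export
#' @examples
#' normalize_name("p38-alpha")  # "p38alpha"
normalize_name <- function(raw) {
  if (length(raw) == 0) return(character(0))
  x <- tolower(trimws(as.character(raw)))
  gsub("[ _./()-]", "", x)
}

#' Build a name index over a kinome table
#'
#' Indexes every non-empty display name, HGNC symbol, UniProt name and
#' alias of every record under its normalized form, tagged with the
#' nomenclature scheme it came from.
#'
#' @param table A [kinome_table()].
#' @return A `name_index`: list with `entries` (named list mapping
#'   normalized key to a data frame of `xname`, `scheme`) and `keys`.
#' @export
build_name_index <- function(table) {
  stopifnot(inherits(table, "kinome_table"))
  xn <- character(0); key <- character(0); scheme <- character(0)
  add <- function(names, sch, owners) {
    keep <- !is.na(names) & nzchar(names)
    xn <<- c(xn, owners[keep])
    key <<- c(key, normalize_name(names[keep]))
    scheme <<- c(scheme, rep(sch, sum(keep)))
  }
  add(table$xname, "manning", table$xname)
  add(table$hgnc_symbol, "hgnc", table$xname)
  add(table$uniprot_name, "uniprot", table$xname)
  n_alias <- lengths(table$aliases)
  if (sum(n_alias) > 0) {
    add(unlist(table$aliases, use.names = FALSE), "alias",
        rep(table$xname, n_alias))
  }
  df <- data.frame(key = key, xname = xn, scheme = scheme,
                   stringsAsFactors = FALSE)
  df <- df[nzchar(df$key), , drop = FALSE]
  df <- df[!duplicated(df[c("key", "xname", "scheme")]), , drop = FALSE]
  entries <- split(df[c("xname", "scheme")], df$key)
  structure(list(entries = entries, keys = names(entries)),
            class = "name_index")
}

# Candidate scoring shared by suggest(); returns integer ranks where
# lower is better, or NA when the key is not a candidate for the query.
match_class_of <- function(query, key, dist) {
  if (key == query) return("exact")
  if (startsWith(key, query)) return("prefix")
  if (grepl(query, key, fixed = TRUE)) return("substring")
  if (nchar(query) >= 4 && dist <= 2) return("fuzzy")
  NA_character_
}

#' Ranked name suggestions
#'
#' Pools exact, prefix, substring and fuzzy (Levenshtein distance <= 2,
#' queries of length >= 4 only) hits against the index keys, deduplicates
#' by kinase keeping the best match class, and ranks by match class
#' (exact < prefix < substring < fuzzy), then scheme priority
#' (manning < hgnc < uniprot < alias), then edit distance, then
#' display name alphabetically.
#'
#' @param query Raw query string (normalized internally).
#' @param index A [build_name_index()] result.
#' @param limit Maximum number of candidates (>= 1).
#' @return Data frame with columns `xname`, `scheme`, `match_class`,
#'   `edit_distance`, ranked best first.
#' @export
suggest_names <- function(query, index, limit = 10L) {
  stopifnot(inherits(index, "name_index"), limit >= 1)
  q <- normalize_name(query)
  empty <- data.frame(xname = character(0), scheme = character(0),
                      match_class = character(0),
                      edit_distance = integer(0), stringsAsFactors = FALSE)
  if (!nzchar(q)) return(empty)

  keys <- index$keys
  dists <- as.integer(utils::adist(q, keys)[1, ])
  cand <- list()
  for (i in seq_along(keys)) {
    mc <- match_class_of(q, keys[i], dists[i])
    if (is.na(mc)) next
    hits <- index$entries[[keys[i]]]
    for (j in seq_len(nrow(hits))) {
      cand[[length(cand) + 1L]] <- list(
        xname = hits$xname[j], scheme = hits$scheme[j],
        match_class = mc, edit_distance = dists[i])
    }
  }
  if (length(cand) == 0) return(empty)
  df <- data.frame(
    xname = vapply(cand, `[[`, character(1), "xname"),
    scheme = vapply(cand, `[[`, character(1), "scheme"),
    match_class = vapply(cand, `[[`, character(1), "match_class"),
    edit_distance = vapply(cand, `[[`, integer(1), "edit_distance"),
    stringsAsFactors = FALSE
  )
  df$mc_rank <- match(df$match_class, MATCH_CLASS_ORDER)
  df$sc_rank <- match(df$scheme, SCHEME_ORDER)
  df <- df[order(df$mc_rank, df$sc_rank, df$edit_distance,
                 df$xname, method = "radix"), , drop = FALSE]
  df <- df[!duplicated(df$xname), , drop = FALSE]
  df <- df[seq_len(min(nrow(df), limit)), , drop = FALSE]
  rownames(df) <- NULL
  df[c("xname", "scheme", "match_class", "edit_distance")]
}

#' Resolve one kinase name against an index
#'
#' An exact normalized-key hit on exactly one distinct kinase resolves
#' uniquely. Hits on two or more kinases, or near-misses with
#' suggestions, yield status `"ambiguous"` with ranked candidates.
#' Otherwise `"unmatched"`.
#'
#' @param query Raw name string.
#' @param index A [build_name_index()] result.
#' @param limit Candidate limit passed to [suggest_names()].
#' @return List with `status` (`"unique"`, `"ambiguous"`,
#'   `"unmatched"`), `match` (xname or `NA`), `candidates` (data frame
#'   as from [suggest_names()]).
#' @export
#' @examples
#' idx <- build_name_index(load_kinome())
#' resolve_name("erbb1", idx)$match  # "EGFR"
resolve_name <- function(query, index, limit = 10L) {
  stopifnot(inherits(index, "name_index"))
  q <- normalize_name(query)
  empty <- suggest_names("", index)
  if (!nzchar(q)) {
    return(list(status = "unmatched", match = NA_character_,
                candidates = empty))
  }
  hit <- index$entries[[q]]
  if (!is.null(hit) && length(unique(hit$xname)) == 1L) {
    sch <- hit$scheme[order(match(hit$scheme, SCHEME_ORDER))][1]
    cand <- data.frame(xname = hit$xname[1], scheme = sch,
                       match_class = "exact", edit_distance = 0L,
                       stringsAsFactors = FALSE)
    return(list(status = "unique", match = hit$xname[1], candidates = cand))
  }
  cand <- suggest_names(query, index, limit = limit)
  if (nrow(cand) == 0) {
    list(status = "unmatched", match = NA_character_, candidates = cand)
  } else {
    list(status = "ambiguous", match = NA_character_, candidates = cand)
  }
}
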