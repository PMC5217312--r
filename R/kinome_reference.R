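# Canonical label sets ---------------------------------------------------

#' Canonical kinase group labels
#'
#' The eight typical groups of the Manning classification in canonical
#' display order, followed by `"Atypical"` for kinases outside the typical
#' groups.
#'
#' @return Character vector of the nine allowed group labels.
#' @export
#' @examples
#' kinase_groups()
kinase_groups <- function() {
  c("AGC", "CAMK", "CK1", "CMGC", "STE", "TK", "TKL", "Other", "Atypical")
}

typical_groups <- function() setdiff(kinase_groups(), "Atypical")

kinome_columns <- function() {
  c("xname", "hgnc_symbol", "uniprot_name", "uniprot_ac",
    "group", "family", "subfamily", "aliases")
}

# Construction and validation --------------------------------------------

#' Construct a kinome classification table
#'
#' Validates a data frame of kinase records and returns it in canonical
#' order: groups in the order given by [kinase_groups()], then family and
#' display name alphabetically (case-insensitive).
#'
#' @param records Data frame with columns `xname`, `hgnc_symbol`,
#'   `uniprot_name`, `uniprot_ac`, `group`, `family`, `subfamily` and
#'   `aliases` (a list column of character vectors).
#' @param source_tag Provenance string, e.g. `"bundled-v1"` or `"synthetic"`.
#' @return A `kinome_table`: the canonical-ordered data frame with a
#'   `source_tag` attribute.
#' @export
kinome_table <- function(records, source_tag = "user") {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(kinome_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("kinome table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0) {
    stop("kinome table must contain at least one record", call. = FALSE)
  }
  records <- records[, kinome_columns()]
  chr_cols <- setdiff(kinome_columns(), "aliases")
  for (col in chr_cols) {
    v <- as.character(records[[col]])
    v[is.na(v)] <- ""
    records[[col]] <- v
  }
  if (!is.list(records$aliases)) {
    records$aliases <- split_aliases(as.character(records$aliases))
  }
  records$aliases <- lapply(records$aliases, function(a) {
    a <- as.character(a)
    a[!is.na(a) & nzchar(a)]
  })

  if (any(!nzchar(records$xname))) {
    stop("every record needs a non-empty xname", call. = FALSE)
  }
  bad_group <- setdiff(unique(records$group), kinase_groups())
  if (length(bad_group) > 0) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(records$family))) {
    stop("every record needs a non-empty family", call. = FALSE)
  }

  key <- vapply(records$xname, normalize_name, character(1))
  if (anyDuplicated(key)) {
    dup <- unique(records$xname[key %in% key[duplicated(key)]])
    stop("duplicate normalized xname(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }

  ord <- order(match(records$group, kinase_groups()),
               tolower(records$family), tolower(records$xname),
               method = "radix")
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  structure(records,
            source_tag = as.character(source_tag)[1],
            class = c("kinome_table", "data.frame"))
}

split_aliases <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, "|", fixed = TRUE)[[1]]
  })
}

#' @export
print.kinome_table <- function(x, ...) {
  cat(sprintf("Kinome table [%s]: %d kinases, %d typical groups, %d atypical families\n",
              attr(x, "source_tag"), nrow(x),
              length(intersect(unique(x$group), typical_groups())),
              length(unique(x$family[x$group == "Atypical"]))))
  invisible(x)
}

# IO ---------------------------------------------------------------------

#' Load a kinome classification table
#'
#' Reads a tab-separated classification table (UTF-8, header row, aliases
#' as a `|`-separated list). With no argument the curated table bundled
#' with the package is loaded.
#'
#' @param path Path to a TSV file, or `NULL` for the bundled table.
#' @return A [kinome_table()] in canonical order.
#' @export
#' @examples
#' kin <- load_kinome()
#' count_taxonomy(kin)
load_kinome <- function(path = NULL) {
  tag <- "bundled-v1"
  if (is.null(path)) {
    path <- system.file("extdata", "human_kinome.tsv", package = "kinotree",
                        mustWork = TRUE)
  } else {
    tag <- paste0("file:", basename(path))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", fill = TRUE,
                           na.strings = NULL, fileEncoding = "UTF-8",
                           check.names = FALSE)
  missing_cols <- setdiff(kinome_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("kinome table file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    stop("kinome table file is empty: ", path, call. = FALSE)
  }
  raw$aliases <- split_aliases(raw$aliases)
  kinome_table(raw, source_tag = tag)
}

#' Write a kinome table as TSV
#'
#' Inverse of [load_kinome()]: `load_kinome(write_kinome_tsv(tab, f))`
#' reproduces `tab` up to its `source_tag`.
#'
#' @param table A [kinome_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kinome_tsv <- function(table, path) {
  stopifnot(inherits(table, "kinome_table"))
  df <- as.data.frame(table)
  df$aliases <- vapply(table$aliases, paste, character(1), collapse = "|")
  lines <- c(paste(kinome_columns(), collapse = "\t"),
             do.call(paste, c(unname(df[kinome_columns()]), sep = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Summaries ---------------------------------------------------------------

#' Summarize the taxonomy of a kinome table
#'
#' Counts kinases, distinct typical groups (excluding `"Atypical"`), and
#' distinct atypical families (families of records with group
#' `"Atypical"`).
#'
#' @param table A [kinome_table()].
#' @return Named list with `n_kinases`, `n_typical_groups`,
#'   `n_atypical_families`.
#' @export
count_taxonomy <- function(table) {
  stopifnot(inherits(table, "kinome_table"))
  list(
    n_kinases = nrow(table),
    n_typical_groups = length(intersect(unique(table$group), typical_groups())),
    n_atypical_families = length(unique(table$family[table$group == "Atypical"]))
  )
}

# Synthetic fixtures -------------------------------------------------------

#' Generate a miniature synthetic kinome
#'
#' Deterministic fixture generator for tests and examples: `n_groups`
#' group labels drawn from the canonical set (cycling past nine), each
#' with `families_per_group` families of `kinases_per_family` kinases.
#' Each record receives 0-3 synthetic aliases.
#'
#' @param n_groups,families_per_group,kinases_per_family Positive counts.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return A [kinome_table()] with `source_tag` `"synthetic"`.
#' @export
#' @examples
#' make_synthetic_kinome(2, 3, 4, seed = 7)
make_synthetic_kinome <- function(n_groups, families_per_group,
                                  kinases_per_family, seed = 0L) {
  counts <- c(n_groups, families_per_group, kinases_per_family)
  if (any(!is.finite(counts)) || any(counts < 1)) {
    stop("all counts must be >= 1", call. = FALSE)
  }
  n_groups <- as.integer(n_groups)
  families_per_group <- as.integer(families_per_group)
  kinases_per_family <- as.integer(kinases_per_family)

  with_seed(seed, {
  groups <- kinase_groups()[((seq_len(n_groups) - 1L) %% 9L) + 1L]
  rows <- list()
  idx <- 0L
  for (g in seq_len(n_groups)) {
    for (f in seq_len(families_per_group)) {
      fam <- sprintf("FAM%d_%d", g, f)
      for (k in seq_len(kinases_per_family)) {
        idx <- idx + 1L
        xn <- sprintf("SKIN%03d", idx)
        n_alias <- sample(0:3, 1)
        aliases <- if (n_alias > 0) {
          sprintf("ALT%03d_%s", idx,
                  replicate(n_alias, paste(sample(LETTERS, 3, TRUE),
                                           collapse = "")))
        } else character(0)
        rows[[idx]] <- list(
          xname = xn,
          hgnc_symbol = sprintf("GENE%03d", idx),
          uniprot_name = "",
          uniprot_ac = "",
          group = groups[g],
          family = fam,
          subfamily = "",
          aliases = aliases
        )
      }
    }
  }
  df <- data.frame(
    xname = vapply(rows, `[[`, character(1), "xname"),
    hgnc_symbol = vapply(rows, `[[`, character(1), "hgnc_symbol"),
    uniprot_name = "",
    uniprot_ac = "",
    group = vapply(rows, `[[`, character(1), "group"),
    family = vapply(rows, `[[`, character(1), "family"),
    subfamily = "",
    stringsAsFactors = FALSE
  )
  df$aliases <- lapply(rows, `[[`, "aliases")
  kinome_table(df, source_tag = "synthetic")
  })
}

# Evaluate `expr` under a seeded RNG, restoring the caller's RNG state
# afterwards. Used by every generator in the package.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% (.Machine$integer.max - 1)))
  expr
}
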