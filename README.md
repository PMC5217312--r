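# kinotree

Annotated maps of the human kinome tree, built locally and
deterministically.

Kinome trees are the standard way to show compound selectivity
profiles, structural coverage, and disease involvement across the
roughly 540 human protein kinases of the Manning classification —
eight typical groups (AGC, CAMK, CK1, CMGC, STE, TK, TKL, Other) plus
13 atypical families. Making such a figure by hand means fighting
three problems at once: every data source names kinases differently;
annotation files need a format that survives editing and exchange; and
the tree itself has to be laid out reproducibly so that two renders of
the same data are the same image. `kinotree` is a desk-scale R library
(plus a small CLI) for exactly that workflow, aimed at
cheminformaticians and kinase biologists who want publication-quality
annotated kinome figures from scripts rather than from a web form.

## What it computes

* **Name resolution.** Every record of the bundled classification
  table is indexed under its Manning display name, HGNC symbol,
  UniProt name, and aliases, all normalized (case-folded; spaces,
  hyphens, underscores, dots, slashes and parentheses stripped).
  A query resolves uniquely on a single exact hit; otherwise ranked
  suggestions are produced from exact, prefix, substring and fuzzy
  (Levenshtein distance ≤ 2, queries of length ≥ 4) candidates,
  ordered by the tuple

  (match class: exact < prefix < substring < fuzzy,
   scheme: Manning < HGNC < UniProt < alias,
   edit distance, name).

* **Marker rescaling.** Annotation sizes can be driven by bioactivity
  values v through a linear or log10 transform t:

  size = s_min + (t(v) − t_min)/(t_max − t_min) · (s_max − s_min),

  reversed under `invert` for lower-is-stronger metrics such as
  dissociation constants; all-equal values map to the midpoint.

* **Radial layout.** The classification hierarchy (group → family →
  subfamily → kinase) is drawn on a circle: after reserving a fixed
  gap per group, each subtree receives angular width proportional to
  its leaf count; anchors sit at span midpoints on per-level radii.
  Atypical kinases are placed in a side-panel grid grouped by family.
  Group spans plus gaps always sum to 2π, and the whole layout is a
  pure function of (table, configuration).

* **Disease-association filtering.** Association records with score
  < 0.1 are excluded, and only records supported by at least one of
  the evidence types genetic, somatic mutation, drug, affected pathway
  or RNA expression are kept.

Annotations travel through four interchangeable formats — a minimal
text grammar with `@` style directives, a CSV schema, an XML export,
and the native JSON `.kmap` state document that reproduces a view
exactly (fonts, zoom, component visibility, interactive mode). Every
writer is paired with a parser and round-trips exactly on the
information the format carries.

## Worked example

```r
library(kinotree)

kin <- load_kinome()
kin
#> Kinome table [bundled-v1]: 453 kinases, 8 typical groups, 13 atypical families

idx <- build_name_index(kin)
res <- resolve_name("erb-b1", idx)   # alias, with a stray hyphen
res$status; res$match
#> "unique"
#> "EGFR"

# a minimal-text annotation document: one style directive, five kinases
doc <- paste(
  "@ shape=circle size=10x10 fill=red stroke=grey",
  "EGFR", "HER2", "ABL1", "SRC", "KDR",
  sep = "\n")
parsed <- parse_minimal_text(doc, idx)
parsed$set
#> Annotation set: 5 annotation(s) on 5 kinase(s)

# an inhibition profile, marker size scaled from Kd (smaller Kd = bigger marker)
profile <- annotation_set(list(
  annotation("EGFR", value = 1.2, unit = "nM", info = c(compound = "erlotinib")),
  annotation("ABL1", value = 25,  unit = "nM", info = c(compound = "erlotinib")),
  annotation("SRC",  value = 380, unit = "nM", info = c(compound = "erlotinib"))))
scaled <- rescale_sizes(profile, size_scale(8, 28, "log10", invert = TRUE))
round(vapply(scaled$annotations, function(a) a$style$width, numeric(1)), 1)
#> [1] 28.0 17.5  8.0

svg <- render_svg(map_state(scaled, interactive = TRUE),
                  layout_kinome(kin), kin)
writeLines(svg, "profile.svg")
```

The three markers sizes (28, 17.5, 8 px) are the log10-inverted map of
the Kd values 1.2, 25 and 380 nM onto [8, 28] px: the most potently
inhibited kinase gets the largest marker. The SVG embeds each
annotation's `info` fields as native tooltip (`<title>`) elements, so
hovering over a marker in a browser shows `compound: erlotinib`.

The same operations are available from a shell:

```sh
Rscript inst/cli/kinotree.R resolve "p38 alpha"
Rscript inst/cli/kinotree.R render --annotations panel.txt --out panel.svg --interactive
Rscript inst/cli/kinotree.R convert panel.txt panel.csv
```

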