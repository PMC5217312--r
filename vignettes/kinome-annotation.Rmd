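---
title: "Annotated kinome maps: models, formats and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotated kinome maps: models, formats and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinotree)
```

This vignette documents how `kinotree` models the human kinome, how
its file formats and layout are defined, and why the open design
choices were made the way they were. It is the package's reference for
everything that is a *decision* rather than a consequence of the data.

## The classification model

The human kinome is partitioned following the Manning scheme: eight
typical groups — AGC, CAMK, CK1, CMGC, STE, TK, TKL and Other — each
subdivided into families and, where the classification is deeper,
subfamilies; kinases outside the typical groups belong to one of 13
atypical families. The package models atypical kinases with the group
label `"Atypical"` and the atypical family name in the `family` field,
because the atypical families function as a partition parallel to the
eight groups, not beneath any of them.

The bundled table (`load_kinome()`) is a curated TSV covering all
eight typical groups with their major families and all 13 atypical
families (A6, ABC1, Alpha, BCR, BRD, FAST, G11, H11, PDHK, PIKK, RIO,
TAF1, TIF1), 453 kinases in total. Exact kinome membership is a
data-curation concern — the classification structure (8 groups, 13
atypical families) is the invariant the package enforces and tests.
Each record carries the Manning-style display name (`xname`, the
unified naming scheme and primary key), the HGNC gene symbol, the
UniProt recommended protein name and accession where curated, and a
`|`-separated alias list. The alias separator is `|` because commas
occur inside protein names. Canonical record order — groups in the
order above with Atypical last, then family and display name
case-insensitively — makes every downstream artifact reproducible
regardless of input row order.

## Name resolution

```{r}
idx <- build_name_index(load_kinome())
resolve_name("p38 alpha", idx)$match
suggest_names("abl", idx, limit = 4)
```

Names are normalized by case-folding, trimming, and deleting spaces,
hyphens, underscores, dots, slashes and parentheses; the operation is
idempotent. Greek letters are deliberately **not** transliterated
(`α` is not rewritten to `alpha`): silent transliteration can match
the wrong isoform, so the alias table carries spelled-out variants
instead (e.g. `p38-alpha` as an alias of p38a).

Suggestion candidates are pooled from four match classes — exact key,
key prefix, key substring, and fuzzy (Levenshtein distance ≤ 2) — and
ranked by the tuple *(match class, scheme priority, edit distance,
name)* with scheme priority Manning > HGNC > UniProt > alias, matching
the order in which the schemes back the display identifier. Fuzzy
matching is restricted to queries of at least 4 characters: for
shorter queries nearly every key is within distance 2 and the
candidate pool degenerates. An exact hit on exactly one kinase
short-circuits the search, so well-formed input pays no fuzzy-scan
cost. The ranking is pinned by a test against a brute-force oracle
that rescores every indexed key with an independently written
edit-distance implementation; the two must agree list-for-list.

## Annotation documents

An annotation is one marker: a target kinase, a style (shape among
circle/square/triangle/diamond/star, width × height in pixels up to
200, fill/stroke colors, stroke width, opacity, optional label), an
optional numeric value with a unit tag, and an ordered `info` map that
feeds tooltips. Colors are accepted as CSS names or `#RRGGBB` and
normalized to upper-case `#RRGGBB` on output so serialized documents
are bit-stable.

Four formats are defined, each writer paired with a parser:

* **Minimal text** — lines of kinase names; a line starting `@` sets
  the style for all following names (`shape=`, `size=WxH`, `fill=`,
  `stroke=`, `stroke_width=`, `opacity=`, `label=` which consumes the
  rest of the line); `#` lines are comments. The default style before
  any directive is a red 15 × 15 circle without stroke. The grammar
  (directive marker, `key=value` tokens, `WxH` sizes) is this
  package's own definition. The format is *documented lossy*: it
  carries styles and names only, and the loss of value/unit/info is
  itself tested.
* **CSV** — RFC 4180, comma delimiter, `.` decimal separator, header
  row; recognized columns `xname` (required), the style columns,
  `value`, `unit`; every other column becomes an `info` entry. Since a
  columnar format has a single global column order, the writer orders
  info columns by a topological merge of the per-annotation key orders
  (first-appearance tie-break): any set whose annotations agree on
  relative key order round-trips exactly, and genuinely conflicting
  orders fall back to first appearance.
* **XML** — one element per annotation with attributes mirroring the
  CSV columns; `info` entries are child elements with a `key`
  attribute because keys like `Kd(nM)` are not valid XML attribute
  names.
* **KMAP** — the native state document: a strict, versioned JSON
  object holding the annotation set plus everything needed to
  reproduce a view (label font, zoom, visible components, interactive
  flag). Unknown top-level fields are rejected and any
  `schema_version` other than 1 raises an unsupported-version error;
  strictness is what makes the round-trip guarantee testable. The
  format is this package's own and makes no compatibility claim
  toward any external tool's files.

Parsing never silently drops a kinase: unresolved names are returned
in a report, and annotation count plus report rows always equals the
number of kinase lines.

## Size rescaling

`rescale_sizes()` maps values through `t` (identity or log10) onto
`[s_min, s_max]`:

$$\mathrm{size} = s_{min} + \frac{t(v) - t_{min}}{t_{max} - t_{min}}\,(s_{max} - s_{min})$$

Two edge rules are deliberate. All-equal values map to the midpoint
`(s_min + s_max)/2`, which avoids a division by zero while keeping
markers visible and symmetric. Lower-is-stronger metrics (Kd, Ki,
IC50) are handled by the explicit `invert` flag rather than by
guessing semantics from the unit string — unit conventions vary too
much across sources for automatic detection to be safe. log10 scaling
refuses non-positive values with an error naming the offending kinase.
Monotonicity and range containment (tolerance 1e-9) are enforced by
property tests over 1,000 random value vectors.

## Tree layout

The tree is drawn from the classification hierarchy, not from
sequence distances: no branch-length data ships with the
classification, so angular width proportional to subtree leaf count is
the principled substitute, and a coordinate-override CSV
(`load_coordinate_table()`) is the escape hatch for users who want to
reproduce externally defined poster coordinates pixel-for-pixel.

Defaults: 1200 × 1000 px canvas, tree radius 420 px, group gap 0.03
rad (visually separates the groups as on the classic poster), start
angle π/2, level radii 0/0.25/0.55/0.8/1 of the tree radius for
root/group/family/subfamily/kinase. Kinases without a subfamily attach
directly at the family level — the classification has ragged depth.
Within a family, subfamily blocks come first (alphabetical), then
direct kinases (alphabetical). Coordinates are SVG-native: origin
top-left, y down; angles are mathematical (0 at +x, counter-clockwise)
before the y flip. Branch paths are three-point polylines
parent → (child angle, parent radius) → child.

Atypical kinases go to a right-hand side panel (220 px wide by
default) in a column-major grid: families alphabetical, each family a
header cell followed by its members, vertical pitch equal to the cell
size and column width five cells. Overflow raises an error suggesting
a larger panel rather than silently clipping.

Determinism is part of the contract: the layout is a pure function of
(table, config); `serialize_layout()` rounds positions to 3 decimals
for byte-identical comparison across platforms; doubling the tree
radius exactly doubles every leaf's distance from the canvas center;
and group spans plus gaps close the full circle to within 1e-9.

## Rendering

`render_svg()` emits SVG 1.1 by deterministic string assembly with a
fixed z-order: branches, group labels, kinase labels, atypical panel,
markers in annotation order (later annotations draw on top), legend.
Components toggled off are absent from the document, not hidden —
element counts shrink, which is testable. Multiple markers on one
kinase are arranged on a deterministic ring of radius half the largest
marker width at that kinase, in annotation order; the collision policy
is this package's choice, made so that overlaid datasets (e.g. two
drugs' profiles) stay distinguishable.

Interactive mode embeds each annotation's `info` map as an SVG
`<title>` child — native browser tooltips — rather than scripting a
viewer: the hover payload survives in a static, testable artifact.
Fonts are referenced by family name only and text is positioned by
anchors, never measured, so output is platform-independent and
byte-identical across runs.

PNG export is an optional capability: SVG is the canonical output, and
`rasterize_png()` delegates to whichever backend is present (the
`rsvg` package or a converter binary), raising an explicit capability
error when none is. The pixel-dimension rule (canvas × dpi/96, rounded)
is a pure function and tested directly.

## Overlays and the association filter

Overlay tables carry per-kinase metrics (structure counts, activity
counts, profiling values) or scored disease associations with evidence
types. The association filter keeps records with score ≥ 0.1 whose
evidence intersects {genetic, somatic_mutation, drug,
affected_pathway, rna_expression}. Two choices are pinned: the
boundary is read literally ("< 0.1 excluded"), so 0.1 itself is kept;
and the cut applies to the single `score` field of this package's
schema (upstream platforms also publish per-datatype scores; this
package's ingest schema has one score per record, documented as such).
Evidence tokens are singular snake_case; a reader alias map accepts
common variants (`"somatic mutations"`, `"drugs"`, `"text_mining"`, …)
because upstream naming varies by source version.

Live extraction from structure/bioactivity/association databases is
out of scope; the CSV schemas are the ingest boundary for real
exports, and `make_synthetic_overlays()` emulates them for tests and
demos.

## What the synthetic data does and does not show

The generators define the test conditions:

* `make_synthetic_kinome(n_groups, families_per_group,
  kinases_per_family, seed)` builds miniature kinomes with generated
  names and 0–3 aliases per record, cycling through the canonical
  group labels.
* `make_synthetic_overlays(table, n_diseases, seed)` draws, per
  kinase, a structure count from a zero-inflated distribution (40%
  exact zeros — mirroring the real kinome, where a large fraction of
  kinases has no experimental structure despite abundant assay data —
  otherwise 1 plus a Poisson with mean 8) and an activity count
  log-uniform in [1, 10000]; per (kinase, disease) pair it includes an
  association with probability 0.1, score uniform in [0, 1], and
  evidence that is literature-only with probability 0.3 and otherwise
  a non-empty subset of the whitelisted types (plus occasional
  non-whitelisted extras). Under these conditions the filter keeps a
  fraction 0.9 × 0.7 = 0.63 in expectation, which the tests check
  within three standard errors — a calibration, not a fit.

What passing tests on synthetic data show: the contracts hold —
round-trips are identities, ranking equals the oracle, the filter
implements its two clauses exactly, layout closes the circle. What
they do not show: real nomenclature collisions beyond those curated in
the bundled table, real score distributions (platform scores are far
from uniform), real evidence co-occurrence, or the actual counts of
any external database version, which shift with every release.

## Problem sizes and numerical conventions

The test suite runs 100 random fixtures per serializer, oracle
comparisons on synthetic kinomes of up to 50 records and 10,000
synthetic association records, and 1,000 random rescale vectors —
sizes chosen so the whole suite completes in well under a minute on a
laptop while leaving the property space densely sampled. Tolerances:
angular closure 1e-9; rescale containment 1e-9; positions rounded to
3 decimals only at serialization (full double precision internally).
Ties everywhere break alphabetically or by first appearance, never by
hash order or locale (all sorts use radix order on lower-cased keys).

## Known limitations

* The bundled table is a curated subset (453 kinases); users needing a
  specific panel can load their own TSV with `load_kinome(path)`.
* The layout is a classification cartoon, not a phylogeny; branch
  lengths carry no evolutionary signal.
* Labels are anchor-positioned; no overlap removal is attempted.
* The KMAP/XML schemas are package-native; no compatibility with any
  external tool's files is claimed.
* PNG export depends on an external rasterizer being installed.
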