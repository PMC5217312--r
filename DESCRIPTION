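Package: kinotree
Title: Annotated Human Kinome Tree Maps
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Build publication-quality annotated maps of the human kinome
    tree from the Manning classification. Resolves kinase names across
    nomenclature schemes (Manning display names, HGNC symbols, UniProt
    names, aliases) with ranked suggestions for incomplete or ambiguous
    queries; parses and writes annotation documents in a minimal text
    grammar, a CSV schema, an XML export, and a native JSON state format;
    rescales marker sizes from bioactivity values; lays out the kinome
    tree deterministically as a radial dendrogram with a side panel for
    atypical kinases; renders annotated SVG images with optional embedded
    tooltips; and filters target-disease association tables by score and
    evidence type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    grDevices,
    stats,
    utils
Suggests:
    rsvg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
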