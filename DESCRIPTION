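Package: lcrevol
Title: Evolutionary Analysis of Low Complexity Regions in Ortholog Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects low complexity regions (homorepeats by sliding-window
    scanning, compositionally biased regions by maximal-segment scoring
    against homopolymers, intrinsically disordered regions from per-residue
    disorder scores, and ingested coiled-coil annotations) in groups of
    aligned orthologous protein sequences; consolidates features onto
    alignment coordinates with per-species conservation profiles; tests
    feature enrichment against a background proteome with exact
    hypergeometric tails; computes Jaccard co-occurrence between feature
    kinds and applies a conserved-alanine-rich filter cascade; and clusters
    proteins or protein fragments by the cross-species overlap of their
    disordered regions. Includes a synthetic ortholog-group generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
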