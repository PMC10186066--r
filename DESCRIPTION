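Package: ogxpand
Title: Hypothesis-Driven Detection and Annotation of Expanded Orthologous Groups
Version: 0.3.0
Authors@R: person("ogxpand", "developers", role = c("aut", "cre"),
    email = "ogxpand@example.org")
Description: Detects gene-family (orthologous-group) expansions between
    user-declared sets of species from Orthofinder-style hierarchical
    orthogroup tables, integrates per-species differential-expression
    evidence, discovers the most similar additional orthogroups via
    reciprocal best hits from all-vs-all protein search tables, and
    provides exact hypergeometric / Fisher over-representation tests for
    orthogroup sets as well as GO-term enrichment over the GO DAG.
    Results are written as an open, subsettable directory bundle of TSV
    tables with a JSON manifest.  Includes a synthetic-data generator
    that plants known expansions, differentially expressed genes and
    enriched GO terms so that every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
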