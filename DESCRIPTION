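Package: dendronym
Title: Cross-Backbone Standardization and Translation of Tree Species Names
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for harmonizing tree species binomials across several
    taxonomic backbones (BGCI, WFO, WCVP and GBIF). Input names are matched
    against a unified, self-contained multi-backbone store through a
    six-stage cascade (exact, genus, fuzzy-genus, exact/suffix/fuzzy epithet
    within genus) built on the optimal string alignment distance. Names that
    cannot be matched directly into a target backbone are re-homed through a
    depth-limited breadth-first search over an undirected synonym graph that
    links binomials via synonym-accepted relations and near-identical
    spellings across all backbones. Matched synonyms are resolved to
    accepted names under a user-defined backbone priority, one species list
    can be translated into another arbitrary list, and ambiguous
    resolutions (homonyms, infraspecific links) are flagged for manual
    review. Includes a deterministic synthetic-backbone generator for
    validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
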