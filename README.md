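# dendronym

Cross-backbone standardization and translation of tree species names.

## The problem

Combining occurrence, trait or inventory data in forest ecology almost
always means reconciling species lists built against different taxonomic
backbones. The major plant checklists — World Flora Online (WFO), the World
Checklist of Vascular Plants (WCVP), the GBIF Backbone Taxonomy, and BGCI's
GlobalTreeSearch — disagree on a large fraction of names: a binomial
accepted in one may be a synonym, a misspelling, or absent in another.
Resolving each list against a single "best" backbone loses data, and
querying backbones one after another can silently produce duplicated taxa
that the first backbone considers synonymous.

`dendronym` treats the synonym information of *all* backbones as one
undirected graph and resolves names by shortest paths in that graph. Every
distinct Latin binomial in the unified store is a vertex with a dense,
reproducible identifier `ID_matched` (its lexicographic rank). Two vertices
are joined when some backbone links them by a synonym→accepted pointer, or
when their full binomials are one optimal-string-alignment edit apart. A
name that cannot be matched directly into a target backbone is re-homed by
a breadth-first search of depth ≤ *d* (default *d* = 3); at the first depth
containing a target-backbone vertex the search stops and the lowest
`ID_matched` vertex is selected, so results are reproducible run to run.

The matching cascade itself has six audited stages, applied in order until
one succeeds: exact binomial; genus presence; fuzzy genus (OSA distance
≤ 1, e.g. *Quecrus* → *Quercus*); then, within the resolved genus, exact
epithet, substitution among the gender endings `a, i, is, um, us, ae`, and
fuzzy epithet (OSA distance ≤ 2). The OSA (restricted Damerau–Levenshtein)
distance counts insertions, deletions, substitutions and adjacent
transpositions as single operations.

## Worked example

The package ships a four-species fixture store encoding a classic
cross-backbone chain: WFO links *Atuna racemosa* → *Atuna excelsa* →
*Parinari racemosa* (accepted), WCVP holds *Parinari racemosa* as a synonym
of *Maranthes corymbosa*, and BGCI contains only *Maranthes corymbosa*.

```r
library(dendronym)
fx <- synonym_chain_fixture()
res <- matching(fx$input, fx$db, backbone = "BGCI")
enf <- enforce_matching(res, fx$db, "BGCI")
enf[, c("Orig.Genus", "Orig.Species", "Matched.Genus", "Matched.Species",
        "matched", "enforced_matching_dist")]
#>   Orig.Genus Orig.Species Matched.Genus Matched.Species matched enforced_matching_dist
#> 1   Parinari     racemosa     Maranthes       corymbosa    TRUE                      1
#> 2      Atuna     racemosa     Maranthes       corymbosa    TRUE                      3
#> 3      Atuna      excelsa     Maranthes       corymbosa    TRUE                      2
#> 4  Maranthes    corymbosa     Maranthes       corymbosa    TRUE                     NA
```

Only *Maranthes corymbosa* matches BGCI directly; the other three are
re-homed through the synonym graph at depths 1, 2 and 3 — the depth records
how many synonym/fuzzy links were crossed, and lets the user trade false
negatives against false positives by filtering on it.

```r
writeLines(summarize_output(enf))
#> matched: 4 / 4 were matched with 1 distinct matched names.
#> direct_match: 1 / 4
#> ...
#> number of species matched via enforce_matching(): 3 / 3
```

Synonyms are resolved to accepted names under a backbone priority order
(`resolve_synonyms`), and one list can be translated onto another arbitrary
list (`translate_trees`):

```r
tf <- translation_fixture()
translate_trees(tf$input, tf$target, tf$db)[, 1:4]
#>   Orig.Genus Orig.Species Matched.Genus Matched.Species
#> 1       Aria    umbellata        Sorbus       umbellata
#> 2    Ardisia     japonica       Ardisia         montana
#> 3      Malus   sylvestris         Malus      orientalis
```

All three inputs land verbatim on the target list even though input and
target disagree with every single backbone. `highlight_flags()` afterwards
reports homonym (`authorship_ambiguity`) and trinomial
(`infraspecific_ambiguity`, `infraspecific_link`) issues per backbone, and
`generate_synthetic_backbones()` produces whole simulated backbone sets
with known ground truth for validation.

Real backbone dumps are ingested with `read_backbone_table()` (Darwin-Core
style headers for WFO/WCVP/GBIF, plain binomial list for BGCI), filtered to
a genus allow-list with `filter_by_genera()`, and closed into a
self-contained store with `close_database()`. A command-line front end
(`inst/cli/dendronym`, subcommands `build-db`, `match`, `enforce`,
`resolve`, `translate`, `flags`, `summarize`, `simulate`) wraps the same
functions for shell pipelines.

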