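---
title: "Methods: graph-based taxonomic name resolution across backbones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-based taxonomic name resolution across backbones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendronym)
```

## The procedure and its assumptions

`dendronym` resolves Latin binomials against a unified store built from up
to four backbones (BGCI, WFO, WCVP, GBIF). The method rests on three
assumptions:

1. **Binomials are the unit of currency.** All matching, graph building
   and resolution happens on normalized (genus, specific epithet) pairs.
   Trinomial *records* from the backbones are retained — they contribute
   graph links and ambiguity flags — but trinomial *inputs* are rejected
   rather than truncated, because the same binomial stem frequently
   resolves to different species depending on its infraspecific epithet.
2. **Synonym pointers are meaningful across backbones.** If backbone A
   says X is a synonym of Y, and backbone B says Y is a synonym of Z, then
   X and Z plausibly refer to the same taxon. The graph search makes this
   transitivity explicit and bounded (the depth limit), rather than
   leaving it implicit in ad-hoc sequential lookups.
3. **Spelling noise is small and local.** Fuzzy matching assumes errors of
   one edit in genera and up to two in epithets; anything farther is
   treated as a different name.

### The unified store

Per-backbone dumps are filtered to species-rank and recognized
infraspecific-rank rows whose status maps into {Accepted, Synonym}
("Homotypic Synonym" and "Heterotypic Synonym" collapse to Synonym; other
statuses such as doubtful or unplaced are dropped and counted). After the
genus allow-list filter, the store is *closed*: synonyms of retained
accepted names are pulled back in even when their genus is outside the
allow-list, and accepted targets of retained synonyms are added likewise.
The two rules iterate to a fixed point, so every pointer in the store
resolves internally; closing a closed store is the identity, which the
test suite asserts on fuzzed inputs.

Every distinct binomial receives `ID_matched`, its 1-based rank in
lexicographic (genus, epithet) order under C collation. Using a computed
rank rather than any source identifier gives a total order that is
invariant under input row order and identical across rebuilds — the
property the deterministic tie-breaks below need.

### The matching cascade

Six stages run in strict order per input row, each only after all earlier
stages failed, and each leaving a logical audit column (`NA` = never
reached): exact binomial; genus presence; fuzzy genus; exact epithet,
suffix substitution, and fuzzy epithet within the resolved genus. Two
subtleties:

* The genus-resolution stages (`genus_match`, `fuzzy_match_genus`) record
  whether a genus was found, not whether the row was finally matched, so a
  row matched by, say, the suffix stage carries `genus_match = TRUE` as
  well. At most one *genus* stage and at most one *match-producing* stage
  can be `TRUE` per row.
* The suffix stage substitutes endings only when the input epithet itself
  terminates in one of `a, i, is, um, us, ae`; the stem is the epithet
  minus that ending. This is the narrow reading of "substituted" — no
  bidirectional stripping — and near-misses simply fall through to the
  fuzzy stage. The six endings are pairwise non-nested, so at most one
  ever applies.

### The synonym graph and enforced matching

Vertices are all distinct binomials; edges come from synonym pointers
(labelled with the providing backbone, trinomial records projected onto
their binomial) and from "fuzzy" links between binomials whose full
strings are at optimal string alignment (OSA) distance exactly 1.

Enforced matching into a target backbone runs a frontier-by-frontier BFS
from each row's vertex. At the first depth whose frontier intersects the
target backbone, the search stops and picks the minimum-`ID_matched` hit.
This implements simultaneously "stop at the first match" and the
reproducible tie-break; monotonicity in the depth limit follows directly
and is property-tested. Rows unmatched anywhere are first re-matched
against the whole store to locate an entry vertex; names absent from the
store pass through unchanged.

`translate_trees()` reuses both machines: stage 1 runs the full cascade
with the target list itself as the only search space; stage 2 matches the
remaining inputs and all target names into the store (a target name
matching several vertices via fuzzy links contributes all of them) and
bridges entry to target vertices by the same BFS. Matched outputs are
always the verbatim target-list spelling.

## Tunable parameters

| Parameter | Default | Rationale |
|---|---|---|
| genus fuzzy threshold (OSA) | 1 | genus names are short and rarely mistyped; a wider net would merge real genera |
| epithet fuzzy threshold (OSA) | 2 | epithets are longer and carry most typos and gender variants |
| suffix set | `a, i, is, um, us, ae` | the common Latin gender/declension endings |
| `max_depth` (enforce / translate) | 3 | depth 1 is strict (direct synonymy only); 3 admits two intermediate names — deeper chains increasingly lump distinct taxa |
| resolution order | BGCI, WFO, WCVP, GBIF | user policy, not consensus: first backbone holding the name wins |

All are surfaced by `matching_defaults()`; the depth and order are
arguments of the respective functions. The fuzzy-edge threshold of the
graph (distance 1 on full binomials) is fixed: it mirrors the genus
threshold's conservatism, since a graph edge — unlike a cascade stage — is
followed transitively.

## Numerical and degenerate-input choices

* **OSA distance** (restricted Damerau–Levenshtein; adjacent
  transpositions cost 1, no substring edited twice) is implemented in
  C++ with a three-row dynamic program. A separately written memoized
  recursion ships alongside purely as a test reference; the suite checks
  both against a pure-R recursion and `utils::adist` bounds, and
  exhaustively on all ~1.2 million string pairs of length ≤ 6 over a
  three-letter alphabet.
* **Comparison is byte-wise on ASCII-folded, case-normalized tokens.**
  Diacritics are transliterated, hybrid markers (`×`, leading `x `)
  stripped before folding, and punctuation residue removed — backbone
  dumps mix encodings, and distance-1 fuzzy matching must not be consumed
  by an accent.
* **Fuzzy-edge blocking.** All-pairs OSA over a large store is quadratic,
  so candidate pairs are generated within blocks: same genus, same
  epithet, or same genus initial with equal total length. A single edit
  either leaves one token intact or is a transposition across the token
  boundary (which preserves the genus initial and total length), so the
  blocks cover every distance-1 pair; the suite verifies this against an
  exhaustive scan on randomized stores including boundary transpositions.
* **Ties.** Fuzzy genus: alphabetical first. Fuzzy epithet: smallest
  distance, then alphabetical. Graph search: lowest `ID_matched` at the
  first hit depth. Every tie that was broken mechanically is surfaced in
  `ambiguity_note` so a curator can intervene.
* **Pointer pathologies.** A pointer whose target is itself a synonym is
  followed transitively with a visited-set cycle guard capped at 10 hops;
  a cycle resolves to its lowest-ID member. Homonymous records that
  resolve differently keep the accepted record if one exists, else the
  lowest-ID candidate — and raise `authorship_ambiguity`.
* **Depth 0.** A row unmatched in the target whose whole-store re-match
  itself lands in the target is recorded with
  `enforced_matching_dist = 0`; the worked examples only exercise depths
  1–3, but the case is reachable through fuzzy re-matching and is
  reported rather than hidden.
* **Empty inputs** (empty query tables, empty stores, backbones without
  metadata) return empty, correctly-shaped results or warn explicitly;
  they never error except where the contract demands it (empty target
  list, `max_depth < 1`).

## The synthetic generator

`generate_synthetic_backbones()` emulates the *disagreement structure* of
real checklists: a shared accepted pool with partial per-backbone overlap
(default 0.8), Poisson-distributed synonym names with valid pointers
(default mean 0.5 per accepted name, echoing the large synonym loads and
roughly 60% cross-checklist agreement of the real backbones), optional
homonymous and infraspecific records, and queries carrying single random
edits at a configurable rate. It deliberately does **not** model
authorship-string formats, rank vocabular drift, nested infraspecific
hierarchies, or realistic nomenclatural history; passing tests on
synthetic data therefore demonstrate mechanical correctness (recovery of
known truth under controlled noise), not fitness of any particular real
backbone snapshot. Generation is a pure function of the parameter set and
seed, and the suite checks determinism, perfect recovery at zero noise,
and accuracy non-decreasing in search depth.

Test problem sizes are kept deliberately modest — stores of 30–80 accepted
species, 200 random graphs of up to 16 vertices for the BFS oracle, the
exhaustive length-≤6 string universe for the distance — chosen so the full
suite exercises every code path in seconds while the properties themselves
are size-independent.

## Known limitations

* Authorship strings are carried as metadata and drive flags, but are not
  parsed or used for disambiguation; truly resolving species-level
  homonyms needs an authority-aware tool downstream.
* Infraspecific inputs are rejected by design; resolving trinomials must
  happen upstream.
* The crosstab counts every distinct binomial in the store, including
  names present only in BGCI — published per-backbone tallies that
  exclude such names will differ in that one cell.
* Fuzzy matching is uniform: it does not weight by name frequency or
  phonetics, and a genuinely new name one edit from a stored name will be
  silently "corrected" (though always with an audit trail).
* Graph edges are unweighted and untyped during search; a fuzzy edge
  counts the same as a curated synonym link.
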