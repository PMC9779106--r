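---
title: "Methods: co-mention networks, entropy/TOPSIS weighting, and collaboration effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-mention networks, entropy/TOPSIS weighting, and collaboration effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnicn)
```

## The problem

When a government announces a cross-cutting policy goal — here, integrating
elderly healthcare with elderly nursing — dozens of ministries, commissions
and public organizations must exchange information to implement it. The
collaboration structure is not directly observable, but it leaves a trace:
policy documents name their issuing agencies and mention the agencies they
task or reference. `hnicn` turns a corpus of such documents into a directed
*information collaboration network* and scores, for every pair of agencies,
how strong their information collaboration is.

The analysis has three stages, run in order by `run_pipeline()`.

## Stage 1: node identification

**Entity recognition.** Agency names are matched against a gazetteer
(`agency_dictionary()`) holding, per agency, a canonical name, aliases
(abbreviations, acronyms, pronouns) and a prefix/middle/tagged-word
decomposition of the name, the tagged word being the institutional type
(Ministry, Commission, ...). `recognize_entities()` finds all literal
occurrences of any surface form and resolves overlaps leftmost-longest, so
a canonical name beats an alias nested inside it. Matching is purely
dictionary-driven: corpus-level features such as word frequency or part of
speech would need training data the package does not assume, and this is a
documented limitation — unlisted pronouns are simply not recognized.

**Edges.** Agencies mentioned together in the same document are taken to
collaborate. Edges are oriented from initiator to receiver: each *issuer*
of a document sends one unit of multiplicity to every *other* agency
appearing in that document, fellow co-issuers included, each ordered pair
at most once per document (`build_network()`). The orientation choice is
supported by the observed data: nodes with zero out-degree are exactly the
agencies that never issue, i.e. pure task receivers. Multiplicities
`m(i, j)` (documents creating the connection) are retained alongside the
binary view `connection(i, j) = 1{m(i, j) >= 1}`.

**Degree centrality.** `degree_centrality()` counts distinct counterparts
on the binary view, separately per direction, and classifies each node:
full (degree >= 20), wide-range (10-19), small-range (5-9), scatter (< 5).
The half-open boundaries are the unique reading consistent with every row
of the published degree tables (degree 20 is full, 10 is wide-range, 5 is
small-range). Thresholds live in `pipeline_config()` and are never
hard-coded at call sites.

## Stage 2: local adjacency subgroups

**Decision matrix.** Mentions are tallied per agency across k = 5 index
aspects (main policies, medical resources, natural resources, economic
support, personnel training / employment encouragement) and min-max
normalized per column into [1, 2] (`normalize_mentions()`). The shift to a
strictly positive range keeps `p log p` terms defined. A zero-spread column
maps to the midpoint 1.5; it carries no discriminating information and
duly receives zero weight downstream. Whether the min-max map should be
per-column or global is not decidable from the published account;
per-column is the default and a `scope = "global"` switch is exposed.

**Index weights** (`entropy_index_weights()`) use the entropy-weight
method: column proportions `p(i, j)`, information entropy
`-(1/ln n) sum p ln p`, utility `1 - entropy`, weights = normalized
utilities. Aspects on which agencies differ most weigh most.

**Node weights** (`topsis_node_weights()`) use standard TOPSIS with all
five aspects treated as benefit-type (more mentions = more engagement;
the method has no cost-type index here): weighted-normalized matrix from
the raw-scale column extrema, Euclidean distances to the ideal and
anti-ideal vectors, closeness `d- / (d- + d+)`, weights = normalized
closeness. A published variant of the anti-ideal distance formula is
garbled in its source; standard TOPSIS is implemented. When a row is at
zero distance from both ideals (all rows identical) closeness is set to
0.5 by convention — every agency is then equally ranked.

**Coverage.** Every node centers an ego subgroup of its distance-1
neighbours in either direction (`build_subgroups()`), each member carrying
`count(member, center)` = total multiplicity between the two, both
directions summed (multiplicity, not the binary view — otherwise the count
would be redundant with membership). Collaboration coverage is the scaled
average weighted link count over members,

`coverage = adj_par * sum_j w_j count(j, center) / (amount - 1)`,

with `adj_par = 10` by default. The summation runs over *members*: that is
the only reading under which the sum varies per subgroup and dividing by
`amount - 1` is an average over members. Coverage is floored at 1.0. The
floor is deliberately applied to the computed value, not only to isolated
centers: in the published table four nodes report coverage exactly 1.00
and structure entropy 0 while having positive in-degree, which a
members-only floor could not produce. The floor also pins the downstream
entropy at its zero point and keeps it non-negative for arbitrary inputs.

## Stage 3: collaboration effect

**Structure entropy.** `cse = coverage * log2(coverage)`
(`collaboration_structure_entropy()`), zero at the coverage floor and
strictly increasing beyond it — a node's tendency to participate in
collaboration. The published formula prints a base-10 logarithm, but base
10 is numerically inconsistent with the published coverage-to-cse column
(43.66 * log10(43.66) is about 71.6 against a printed 237.84), while base
2 reproduces all 22 rows to within 0.05. The package therefore defaults to
base 2 and exposes `cse_log_base` in the configuration; the discrepancy is
documented rather than silently resolved.

**Effect.** For each unordered pair, the effect is `cse_i * cse_j`
normalized by the maximum product M over all pairs, as a percentage; the
pair(s) attaining M are damped to `M / (M + psi)` with `psi = 10000` so no
value reaches 100% (`collaboration_effect_matrix()`). If several pairs tie
at M, all are damped — the case split is on the product equalling the
maximum, not on pair identity. Diagonal pairs are excluded. Note the
damping is order-preserving only when `psi` is small relative to M;
with the default psi and realistic cse magnitudes the damped maximum stays
the top-ranked pair. `rank_effects()` sorts pairs descending, ties broken
by natural code order (A3 before A14), which matches the published pair
labels.

## Synthetic data and what it validates

The real corpus (484 documents from 12 ministry websites) is not
redistributable, so `generator_spec()` / `generate_corpus()` emulate its
statistical shape: 22 agencies (3 public organizations), 484 documents
within the 23 Oct 2019 - 1 Feb 2022 window, 5 aspects, and two planted
hubs. Hub dominance uses a deliberate two-tier mechanism rather than
preferential attachment — the observed network is two-hub dominated, and
two tiers are the minimal mechanism reproducing that: hubs issue with
probability 0.5 per document versus 0.04 for the background (a 12.5x
ratio), and are 20x more likely to be drawn as mention targets. Mentions
per document are `1 + Poisson(3)` (mean 4); each mention independently
uses an alias with probability 0.25 and is assigned one aspect, uniform by
default with an optional skew — the published account never states how a
mention maps to an aspect. All randomness flows from the single spec seed
through one restored-on-exit RNG stream; identical spec and seed give
bit-identical output. The generator emits exact ground truth (planted
multiplicities, per-agency aspect counts, hub identity) so the pipeline
can be checked end to end: `build_network()` must recover the planted
multiplicities exactly, and `run_recovery_study()` must rank the planted
hubs first and second by coverage in at least 95% of seeds (validated over
100 seeds at 300 documents each; a shuffled-rank mode provides the chance
baseline of 2 in n(n-1) for comparison).

What the generator does *not* emulate: natural-language document text
(bodies are templated sentences embedding the surface forms), semantic
aspect structure, temporal drift within the window, and real-world agency
name ambiguity. Passing tests therefore demonstrate the pipeline's
correctness and its ability to recover planted structure — not that the
recognition dictionary or aspect tally would be adequate for an arbitrary
real corpus.

## Reference data and reproduction scale

The published summary tables of the 22-agency network ship under
`inst/extdata` and load through `hnicn_fixture()`: the agency roster,
degree centrality, index weights, node weights, coverage/cse, and top-10
effects. The raw decision matrix and edge list were never published, so
the entropy column, the coverage column and the degrees cannot be
recomputed from first principles; they serve as *inputs* from which every
downstream quantity is recomputed, and the unpublished stages are covered
by brute-force oracle equivalence (degree centrality against materialized
adjacency matrices on networks of up to 8 nodes; TOPSIS against an
independently coded step-by-step evaluation on random 5x3 matrices, at
1e-12) and invariant suites (weights sum to one, effect symmetry and
boundedness, coverage floor). A synthetic stand-in network realizing the
published out/in degree sequences exactly is built by a greedy
degree-sequence construction (`generate_network_from_degrees()`) for
export and classification tests. One published quirk is normalized
deliberately: the rank-22 row of the coverage table is labelled
inconsistently with the roster, and the roster (B3 = Red Cross Society)
is followed.

Two numerical notes on reproducing printed values from printed inputs:
recomputing the A12-A14 effect from the 2-decimal printed cse column lands
within 0.0006 of the printed percentage (the original computation used
unrounded cse), and recomputing all 22 closeness values from the 3-decimal
printed distances deviates by up to 0.0012 on one row for the same reason.
Tests assert these at tolerances that reflect input rounding, never wider.

## Degenerate inputs and errors

Duplicate codes, colliding surface forms, empty issuer sets, unknown
mention codes, out-of-window dates, negative degrees, non-positive
`adj_par`/`psi`, all-zero cse vectors and unrealizable degree sequences
are all hard errors naming the offender. Empty corpora, isolated nodes,
matchless text and header-only files are valid and return empty results.
Pipeline stage failures abort naming the failing stage.
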