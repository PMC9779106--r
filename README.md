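# hnicn

Inter-agency information collaboration networks from policy documents.

When many government agencies must jointly implement a cross-cutting policy
goal — the motivating case is the integration of elderly healthcare and
elderly nursing in China — their collaboration structure leaves a trace in
the policy documents they issue: each document names its issuers and
mentions the agencies it tasks. `hnicn` turns such a corpus into a directed
co-mention network and quantifies, for every pair of agencies, the strength
of their information collaboration. It is aimed at computational
social-science and policy-informatics researchers working with
document-derived collaboration networks.

## The method

Three stages, orchestrated by `run_pipeline()`:

1. **Node identification.** Dictionary-based entity recognition
   (leftmost-longest gazetteer matching over canonical names and aliases),
   then a directed edge from every issuer *i* to every other agency *j*
   co-appearing in the same document, with multiplicity m(i, j) = number of
   such documents. Degree centrality on the binary view,
   deg⁺(i) = Σ_j 1{m(i, j) ≥ 1}, classifies nodes into full (≥ 20),
   wide-range [10, 20), small-range [5, 10) and scatter (< 5) connection
   types.

2. **Local adjacency subgroups.** Per-aspect mention counts are min-max
   normalized into [1, 2]; the entropy-weight method turns them into index
   weights w_j ∝ 1 − entropy_j, and TOPSIS (closeness to the ideal
   solution, c_i = d⁻/(d⁻ + d⁺)) into node weights. Every node centers an
   ego subgroup of its distance-1 neighbours; its *collaboration coverage*
   is `adj_par · Σ_j w_j count(j, center) / (amount − 1)`, floored at 1,
   with adj_par = 10.

3. **Effect measurement.** Collaboration structure entropy
   cse = coverage · log₂(coverage), then the pairwise effect
   `effect(i, j) = cse_i·cse_j / M` (as a percentage), where M is the
   maximum product over pairs; the maximal pair is damped to `M / (M + ψ)`,
   ψ = 10,000, so no value reaches 100%.

A synthetic-corpus generator with planted hubs and exact ground truth
(`generator_spec()`, `generate_corpus()`) makes every stage testable
without the original corpus, and the published summary tables of the
22-agency healthcare–nursing network ship as reference data
(`hnicn_fixture()`).

## Worked example

Scoring the bundled 22-agency network from its published coverage table:

```r
library(hnicn)

cv  <- hnicn_fixture("coverage")                     # 22 nodes
cse <- setNames(cv$cse, cv$code)
eff <- collaboration_effect_matrix(cse, psi = 10000)
rank_effects(eff, top_n = 3)
#>   rank code_i code_j    pair effect_percent
#> 1    1     A1    A14  A1-A14       84.57204
#> 2    2    A11    A14 A11-A14       20.27508
#> 3    3     A1    A11  A1-A11       19.64766
```

The National Health Commission (A1) and the Ministry of Industry and
Information Technology (A14) collaborate far more strongly (84.572%) than
any other pair; the runner-up, traditional-medicine administration with
MIIT, reaches only 20.275%. The structure entropy underlying those scores
comes from the coverage column:

```r
round(collaboration_structure_entropy(c(43.66, 42.58, 1.00)), 2)
#> [1] 237.87 230.45   0.00
```

A fully synthetic run — generate a hub-dominated corpus, recover the
network, weight the nodes, score the pairs:

```r
spec <- generator_spec(n_docs = 300, seed = 7)
dict <- generate_dictionary(spec)
gen  <- generate_corpus(spec, dict)
mm   <- generate_mention_matrix(spec, gen$ground_truth)
res  <- run_pipeline(pipeline_config(), dictionary = dict,
                     corpus = gen$corpus, mentions = mm)
res
#> <hnicn_results> 22 nodes, 397 directed pairs
#>   top pair: A1-A2 (88.324%)
```

The planted hubs (A1, A2) end up as the top coverage pair, mirroring the
two-hub dominance of the reference network. `write_results_tables(res,
"out/")` emits the degree, weight, coverage and effect tables as CSV;
`export_network(res$network, "gexf", "net.gexf", dict)` writes a
Gephi-loadable graph. A thin command-line front end lives in
`exec/hnicn` (`synth`, `nis`, `lass`, `icems`, `run`, `recover`).

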