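Package: hnicn
Title: Inter-Agency Information Collaboration Networks from Policy Documents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses directed co-mention networks of government
    agencies extracted from policy-document corpora. Implements a three-stage
    pipeline: dictionary-based entity recognition with issuer-to-receiver edge
    construction and degree-centrality classification (node identification);
    entropy-weight and TOPSIS scoring of agencies combined with ego-subgroup
    collaboration coverage (local adjacency subgroups); and an information-
    entropy based pairwise collaboration-effect measure (collaboration effect
    measurement). Includes a synthetic corpus generator with planted hubs and
    ground truth for end-to-end validation, readers and writers for the
    tabular, JSONL, GEXF and GraphML formats the pipeline touches, and the
    published summary tables of a 22-agency healthcare-nursing collaboration
    network as bundled reference data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
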