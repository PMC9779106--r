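test_that("documents outside the retrieval window are dropped and counted", {
  dict <- tiny_dictionary()
  corpus <- list(
    doc("D1", "A1", "A2", dict, date = "2020-01-15"),
    doc("D2", "A2", "A3", dict, date = "2021-12-31"),
    doc("D3", "A1", "A2", dict, date = "2019-09-01"))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, f)
  expect_message(back <- read_corpus(f, dict), "dropped 1 document")
  expect_length(back, 2L)
  expect_setequal(vapply(back, `[[`, character(1), "doc_id"), c("D1", "D2"))
  # window endpoints are inclusive
  corpus2 <- list(doc("E1", "A1", "A2", dict, date = "2019-10-23"),
                  doc("E2", "A1", "A2", dict, date = "2022-02-01"))
  write_corpus(corpus2, f)
  expect_silent(back2 <- read_corpus(f, dict))
  expect_length(back2, 2L)
})

test_that("malformed records are rejected with the offending doc_id", {
  dict <- tiny_dictionary()
  expect_error(policy_document("X1", "2020-01-01", character(0),
                               text = "t"), "no issuers")
  expect_error(policy_document("X2", "2020-01-01", "A1"), "neither")
  bad_issuer <- doc("X3", "A9", "A2", dict)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(list(bad_issuer), f)
  expect_error(read_corpus(f, dict), "unknown issuer.*A9")
  bad_mention <- policy_document(
    "X4", "2020-01-01", "A1",
    mentions = data.frame(surface = "Nope Agency", code = "Z9"))
  write_corpus(list(bad_mention), f)
  expect_error(read_corpus(f, dict), "X4.*Z9")
})

test_that("a synthetic corpus round-trips through JSONL unchanged", {
  spec <- generator_spec(n_agencies = 6, n_docs = 25, seed = 11)
  dict <- generate_dictionary(spec)
  corpus <- generate_corpus(spec, dict)$corpus
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, f)
  back <- read_corpus(f, dict)
  expect_length(back, length(corpus))
  for (k in seq_along(corpus)) {
    expect_equal(back[[k]]$doc_id, corpus[[k]]$doc_id)
    expect_equal(back[[k]]$date, corpus[[k]]$date)
    expect_equal(back[[k]]$issuers, corpus[[k]]$issuers)
    expect_equal(back[[k]]$mentions, corpus[[k]]$mentions)
    expect_equal(back[[k]]$text, corpus[[k]]$text)
    expect_equal(back[[k]]$aspect_counts, corpus[[k]]$aspect_counts)
  }
})

test_that("network export formats serialize and re-read consistently", {
  dict <- tiny_dictionary()
  # direct serialization of a 2-node network
  net <- collab_network(data.frame(source = "A1", target = "A2",
                                   multiplicity = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  export_network(net, "edge-list-csv", f)
  expect_equal(readLines(f), c("source,target,multiplicity", "A1,A2,3"))

  expect_error(export_network(net, "dot", f), "edge-list-csv")
  empty <- collab_network(data.frame(), nodes = c("A1", "A2"))
  expect_error(export_network(empty, "gexf", f), "no edges")

  # the degree-sequence reference network: 22 nodes in GEXF and GraphML
  deg <- hnicn_fixture("degree_centrality")
  ref <- generate_network_from_degrees(deg$out_degree, deg$in_degree,
                                       deg$code)
  gexf <- withr::local_tempfile(fileext = ".gexf")
  export_network(ref, "gexf", gexf, dict = hnicn_fixture("agencies"))
  x <- xml2::read_xml(gexf)
  expect_length(xml2::xml_find_all(x, "//*[local-name()='node']"), 22L)
  expect_length(xml2::xml_find_all(x, "//*[local-name()='edge']"),
                nrow(ref$edges))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(ref, "graphml", gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 22)
  expect_setequal(igraph::V(g)$code, ref$nodes)
  el <- igraph::as_edgelist(g)
  got <- sort(paste(igraph::V(g)$code[match(el[, 1], igraph::V(g)$name)],
                    igraph::V(g)$code[match(el[, 2], igraph::V(g)$name)]))
  expect_equal(got, sort(paste(ref$edges$source, ref$edges$target)))
})

test_that("result tables are written with the reported precision", {
  cv <- hnicn_fixture("coverage")
  cse <- collaboration_structure_entropy(cv$coverage)
  coverage <- data.frame(code = cv$code, coverage = cv$coverage, cse = cse)
  effects <- collaboration_effect_matrix(setNames(cv$cse, cv$code))
  results <- list(coverage = coverage, effects = effects,
                  manifest = list(config = list(top_n = 10L)))
  out <- withr::local_tempdir()
  paths <- write_results_tables(results, out)
  covtab <- read.csv(paths[["coverage"]])
  expect_equal(covtab$code[1], "A14")
  expect_equal(covtab$cse[1], 237.84, tolerance = 0.05 / 237.84)
  top <- read.csv(paths[["top_effects"]])
  expect_equal(nrow(top), 10L)
  expect_equal(top$pair[1], "A1-A14")
  expect_match(as.character(top$effect_percent[1]), "^84\\.572$")
  # header-only files for an empty bundle
  out2 <- withr::local_tempdir()
  paths2 <- write_results_tables(list(), out2)
  for (p in paths2) expect_length(readLines(p), 1L)
  # top_n = 1 keeps a single pair
  paths3 <- write_results_tables(results, withr::local_tempdir(), top_n = 1)
  expect_equal(nrow(read.csv(paths3[["top_effects"]])), 1L)
})
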