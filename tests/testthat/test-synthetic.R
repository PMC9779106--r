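test_that("generation is deterministic given spec and seed", {
  spec <- generator_spec(n_agencies = 2, n_docs = 10, seed = 7)
  d1 <- generate_dictionary(spec)
  d2 <- generate_dictionary(spec)
  expect_identical(d1, d2)
  g1 <- generate_corpus(spec, d1)
  g2 <- generate_corpus(spec, d1)
  expect_identical(g1, g2)
  # a different seed changes the draw
  spec2 <- generator_spec(n_agencies = 2, n_docs = 10, seed = 8)
  expect_false(identical(generate_corpus(spec2, generate_dictionary(spec2)),
                         g1))
  # generator does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_corpus(spec, d1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("dictionary generation honours the requested roster shape", {
  spec <- generator_spec(n_agencies = 22, seed = 1)
  dict <- generate_dictionary(spec)
  expect_equal(nrow(dict$entries), 22L)
  expect_false(anyDuplicated(dict$entries$code) > 0)
  expect_equal(sum(dict$entries$category == "public-organization"), 3L)
  expect_true(all(lengths(dict$entries$aliases) >= 1 &
                  lengths(dict$entries$aliases) <= 3))
  expect_true(all(nzchar(dict$entries$tagged)))
})

test_that("alias_rate zero produces a corpus of canonical surfaces only", {
  spec <- generator_spec(n_agencies = 8, n_docs = 60, alias_rate = 0,
                         seed = 9)
  dict <- generate_dictionary(spec)
  gen <- generate_corpus(spec, dict)
  surfaces <- unlist(lapply(gen$corpus, function(d) d$mentions$surface))
  expect_true(all(surfaces %in% dict$entries$canonical_name))
  expect_equal(gen$ground_truth$alias_mentions, 0L)
  # and text-based recognition recovers every planted mention code
  for (d in gen$corpus[1:10]) {
    hits <- recognize_entities(d$text, dict)
    expect_equal(sort(unique(hits$code)), sort(unique(d$mentions$code)))
  }
  # a positive alias rate does use aliases
  spec2 <- generator_spec(n_agencies = 8, n_docs = 60, alias_rate = 0.8,
                          seed = 9)
  gen2 <- generate_corpus(spec2, generate_dictionary(spec2))
  expect_gt(gen2$ground_truth$alias_mentions, 0L)
})

test_that("edge cases: empty corpus, zero activity, bad hubs", {
  spec <- generator_spec(n_agencies = 5, n_docs = 0, seed = 2)
  dict <- generate_dictionary(spec)
  gen <- generate_corpus(spec, dict)
  expect_length(gen$corpus, 0L)
  expect_equal(nrow(gen$ground_truth$multiplicity), 0L)
  expect_true(all(gen$ground_truth$aspect_counts == 0))
  zero <- spec
  zero$issuer_activity[] <- 0
  expect_error(generate_corpus(zero, dict), "zero")
  expect_error(generator_spec(n_agencies = 5, hub_codes = "Z9"), "codes")
  expect_error(generator_spec(n_agencies = 5, hub_activity = 0.1,
                              base_activity = 0.2), "strictly greater")
})

test_that("ground-truth aspect counts conserve corpus mentions", {
  spec <- generator_spec(n_agencies = 10, n_docs = 100, seed = 13)
  dict <- generate_dictionary(spec)
  gen <- generate_corpus(spec, dict)
  total_mentions <- sum(vapply(gen$corpus,
                               function(d) nrow(d$mentions), integer(1)))
  expect_equal(sum(gen$ground_truth$aspect_counts), total_mentions)
  # per-document aspect counts sum to that document's mention count
  for (d in gen$corpus[1:10]) {
    expect_equal(sum(d$aspect_counts), nrow(d$mentions))
  }
  # column sums equal total per-aspect mentions
  mm <- generate_mention_matrix(spec, gen$ground_truth)
  expect_equal(colSums(mm$raw), colSums(gen$ground_truth$aspect_counts))
  expect_true(all(mm$normalized >= 1 & mm$normalized <= 2))
  # planted multiplicity bounded by documents x (issuers x mentions) cap
  expect_lte(sum(gen$ground_truth$multiplicity$multiplicity),
             length(gen$corpus) * spec$n_agencies^2)
})

test_that("constant planted columns normalize to the 1.5 midpoint", {
  gt <- structure(list(multiplicity = data.frame(),
                       aspect_counts = cbind(a = c(4, 4, 4),
                                             b = c(0, 5, 10)),
                       hub_codes = "A1", alias_mentions = 0L),
                  class = "hnicn_ground_truth")
  mm <- generate_mention_matrix(generator_spec(n_agencies = 3, seed = 1), gt)
  expect_equal(unname(mm$normalized[, "a"]), rep(1.5, 3))
  expect_equal(unname(mm$normalized[, "b"]), c(1.0, 1.5, 2.0))
})

test_that("greedy degree realization matches requested sequences", {
  # the published out/in sequences are realizable
  deg <- hnicn_fixture("degree_centrality")
  net <- generate_network_from_degrees(deg$out_degree, deg$in_degree,
                                       deg$code)
  got <- degree_centrality(net)
  expect_equal(got$out_degree, deg$out_degree)
  expect_equal(got$in_degree, deg$in_degree)
  expect_true(all(net$edges$source != net$edges$target))
  expect_error(generate_network_from_degrees(c(2, 0), c(1, 0)), "sums")
})
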