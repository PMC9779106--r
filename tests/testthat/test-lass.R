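test_that("min-max normalization maps counts into [1, 2] per column", {
  m <- normalize_mentions(cbind(a = c(0, 5, 10), b = c(4, 4, 4)))
  expect_equal(unname(m$normalized[, "a"]), c(1.0, 1.5, 2.0))
  expect_equal(unname(m$normalized[, "b"]), c(1.5, 1.5, 1.5))
  set.seed(3)
  for (rep in 1:10) {
    raw <- matrix(rpois(18, 20), nrow = 6)
    nm <- normalize_mentions(raw)$normalized
    expect_true(all(nm >= 1 & nm <= 2))
    expect_equal(unname(apply(nm, 2, min)), rep(1, 3))
    expect_equal(unname(apply(nm, 2, max)), rep(2, 3))
  }
  expect_error(normalize_mentions(matrix(1, 1, 3)), "at least 2")
  expect_error(normalize_mentions(matrix(-1, 3, 2)), "non-negative")
  # global scope uses matrix-wide extrema
  g <- normalize_mentions(cbind(c(0, 10), c(5, 20)), scope = "global")
  expect_equal(unname(g$normalized[, 1]), c(1, 1.5))
})

test_that("entropy weights follow the proportion/entropy/utility chain", {
  # uniform column attains maximum entropy 1, zero utility
  m <- cbind(u = c(1.5, 1.5, 1.5, 1.5), v = c(1, 1.2, 1.7, 2))
  iw <- entropy_index_weights(m)
  expect_equal(iw$inf_entropy[1], 1)
  expect_equal(iw$inf_utility[1], 0)
  expect_equal(iw$inf_utility, 1 - iw$inf_entropy)
  expect_equal(sum(iw$weight_index), 1)
  p <- attr(iw, "p")
  expect_equal(unname(colSums(p)), rep(1, 2))
  expect_true(all(iw$inf_entropy >= 0 & iw$inf_entropy <= 1))
  expect_error(entropy_index_weights(matrix(1.5, 1, 2)), "at least 2")
  # published utilities renormalize to the published weights
  ref <- hnicn_fixture("index_weights")
  expect_true(all(abs(ref$inf_utility / sum(ref$inf_utility) -
                      ref$weight_index) <= 0.001))
})

test_that("TOPSIS agrees with an independently coded oracle to 1e-12", {
  set.seed(23)
  for (rep in 1:20) {
    raw <- matrix(rpois(15, 30), nrow = 5)
    mm <- normalize_mentions(raw)
    iw <- entropy_index_weights(mm)
    nw <- topsis_node_weights(mm, iw)
    want <- topsis_oracle(mm$normalized, iw$weight_index)
    expect_equal(nw$dis_plus, want$dis_plus, tolerance = 1e-12)
    expect_equal(nw$dis_minus, want$dis_minus, tolerance = 1e-12)
    expect_equal(nw$closeness, want$close, tolerance = 1e-12)
    expect_equal(nw$weight_node, want$weight, tolerance = 1e-12)
    expect_equal(sum(nw$weight_node), 1, tolerance = 1e-9)
    expect_true(all(nw$closeness >= 0 & nw$closeness <= 1))
  }
})

test_that("closeness limits and degenerate rows behave as defined", {
  expect_equal(relative_closeness(0.159, 0.384), 0.707, tolerance = 1e-3)
  expect_equal(relative_closeness(0.5, 0), 0)   # at the anti-ideal
  expect_equal(relative_closeness(0, 0.5), 1)   # at the ideal
  expect_equal(relative_closeness(0, 0), 0.5)   # all rows identical
  # all-identical rows: every node equally close
  mm <- normalize_mentions(matrix(c(2, 2, 2, 5, 5, 5), nrow = 3))
  iw <- suppressWarnings(entropy_index_weights(mm))
  nw <- topsis_node_weights(mm, iw)
  expect_equal(nw$closeness, rep(0.5, 3))
})

test_that("published closeness column renormalizes to node weights", {
  ref <- hnicn_fixture("node_weights")
  w <- node_weights_from_closeness(ref$closeness)
  expect_true(all(abs(w - ref$weight_node) <= 0.001))
  expect_equal(w[ref$code == "A1"], 0.188, tolerance = 0.001 / 0.188)
  expect_equal(w[ref$code == "A2"], 0.153, tolerance = 0.001 / 0.153)
  expect_equal(w[ref$code == "A15"], 0.043, tolerance = 0.001 / 0.043)
})

test_that("subgroups are distance-1 ego clusters with summed link counts", {
  net <- star_network(k = 5, m = 2)
  subs <- build_subgroups(net)
  expect_equal(subs[["HUB"]]$amount, 6L)
  expect_setequal(subs[["HUB"]]$members, paste0("L", 1:5))
  expect_equal(unname(subs[["L1"]]$link_counts), 2)
  expect_equal(subs[["L1"]]$amount, 2L)
  expect_equal(subs[["ISO"]]$amount, 1L)
  expect_length(subs[["ISO"]]$members, 0L)
  # membership equals the adjacency-scan oracle m(i,j) + m(j,i) >= 1
  set.seed(31)
  rnd <- random_network(7, p = 0.35)
  subs2 <- build_subgroups(rnd)
  for (c_node in rnd$nodes) {
    want <- vapply(setdiff(rnd$nodes, c_node), function(j) {
      e <- rnd$edges
      sum(e$multiplicity[(e$source == c_node & e$target == j) |
                         (e$source == j & e$target == c_node)])
    }, numeric(1))
    expect_setequal(subs2[[c_node]]$members, names(want[want >= 1]))
    expect_equal(subs2[[c_node]]$link_counts,
                 want[sort(names(want[want >= 1]))])
  }
})

test_that("collaboration coverage evaluates the averaged weighted counts", {
  nw <- data.frame(code = c("M1", "M2", "C"),
                   weight_node = c(0.2, 0.3, 0.5))
  single <- structure(list(center = "C", members = "M1",
                           link_counts = c(M1 = 3), amount = 2L),
                      class = "subgroup")
  expect_equal(collaboration_coverage(single, nw, adj_par = 10), 6.0)
  nw2 <- data.frame(code = c("M1", "M2"), weight_node = c(0.1, 0.3))
  two <- structure(list(center = "C", members = c("M1", "M2"),
                        link_counts = c(M1 = 2, M2 = 1), amount = 3L),
                   class = "subgroup")
  # 10 * (0.1*2 + 0.3*1) / 2
  expect_equal(collaboration_coverage(two, nw2, adj_par = 10), 2.5)
  # linear in adj_par
  expect_equal(collaboration_coverage(two, nw2, adj_par = 20), 5.0)
  expect_error(collaboration_coverage(two, nw, adj_par = 0), "positive")
  # isolated center takes the floor value 1
  iso <- structure(list(center = "C", members = character(0),
                        link_counts = numeric(0), amount = 1L),
                   class = "subgroup")
  expect_equal(collaboration_coverage(iso, nw), 1.0)
})
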