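small_bundle <- function(seed = 2, n_herbs = 12, n_targets = 15) {
  simulate_kg(kg_sim_config(
    n_herbs = n_herbs, n_targets = n_targets, n_auxiliary = 0,
    n_herb_target_edges = 3 * n_herbs, n_auxiliary_edges = 0,
    n_attributes = 6, n_ontology_terms = 3, n_herb_pair_rules = 1,
    n_attribute_pair_rules = 1, n_pathways = 0), seed = seed)
}

test_that("sampling is reproducible and respects the combination contract", {
  b <- small_bundle()
  s1 <- sample_combinations(b$graph, 3, 50, seed = 9)
  s2 <- sample_combinations(b$graph, 3, 50, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(vapply(s1, length, integer(1)) == 3))
  expect_true(all(vapply(s1, anyDuplicated, integer(1)) == 0))
  # dedupe by canonical form within the draw
  keys <- vapply(s1, paste, character(1), collapse = "|")
  expect_false(anyDuplicated(keys) > 0)

  expect_error(sample_combinations(b$graph, 99, 1, seed = 1),
               "cannot draw")
})

test_that("a graph with exactly x herbs yields the single possible combination", {
  b <- small_bundle(n_herbs = 4)
  s <- sample_combinations(b$graph, 4, 1, seed = 1)
  expect_equal(s[[1]], sort(b$graph$herbs$id))
})

test_that("per-herb inclusion frequency is uniform at 8/345", {
  herbs <- data.frame(id = sprintf("H%03d", 1:345),
                      name = sprintf("h%03d", 1:345))
  g <- knowledge_graph(herbs,
                       targets = data.frame(id = "T1", name = "t1"))
  draws <- sample_combinations(g, 8, 1000, seed = 2024, dedupe = FALSE)
  counts <- table(factor(unlist(draws), levels = herbs$id))
  p <- 8 / 345
  se <- sqrt(1000 * p * (1 - p))
  dev <- abs(as.numeric(counts) - 1000 * p)
  # all herbs close to uniform; a few 3-sigma excursions tolerated among 345
  expect_lt(max(dev), 4.5 * se)
  expect_gte(mean(dev <= 3 * se), 0.98)
})

test_that("a one-round search reproduces hand-ranked scores", {
  b <- small_bundle(seed = 8)
  cfg <- search_config(x = 3, rounds = 1, combos_per_round = 5, top_k = 3,
                       seed = 17)
  sr <- run_search(b$graph, b$rules, b$evidence, cfg)
  combos <- sample_combinations(b$graph, 3, 5, seed = 17 + 1)
  hand <- vapply(combos, function(cb)
    score_combination(b$graph, cb, b$rules, b$evidence)$total, numeric(1))
  keys <- vapply(combos, paste, character(1), collapse = "|")
  ord <- order(-hand, keys, method = "radix")
  expect_equal(sr$rounds[[1]]$scored$key, keys[ord])
  expect_equal(sr$rounds[[1]]$scored$total, hand[ord], tolerance = 1e-12)
  expect_equal(sr$rounds[[1]]$top_k_keys,
               keys[ord][hand[ord] > 0][seq_len(min(3, sum(hand > 0)))])
})

test_that("search results are bit-identical across reruns", {
  b <- small_bundle(seed = 21)
  cfg <- search_config(x = 3, rounds = 3, combos_per_round = 40, top_k = 5,
                       seed = 5)
  expect_identical(run_search(b$graph, b$rules, b$evidence, cfg),
                   run_search(b$graph, b$rules, b$evidence, cfg))
})

test_that("universally violated rules empty the top-k and consensus", {
  g <- knowledge_graph(
    herbs = data.frame(id = c("H1", "H2", "H3"), name = c("a", "b", "c"),
                       attributes = "toxic"),
    targets = data.frame(id = paste0("T", 1:5), name = paste0("t", 1:5)),
    relations = data.frame(herb_id = c("H1", "H2", "H3"),
                           target_id = c("T1", "T2", "T3"),
                           ontology_term = "acts_on", provenance = ""))
  rules <- data.frame(kind = "attribute_pair", left = "toxic",
                      right = "toxic", note = "")
  ev <- data.frame(herb_id = c("H1", "H2", "H3"), c2 = 1, l = 5, j = 1, k = 1)
  cfg <- search_config(x = 2, rounds = 2, combos_per_round = 3, top_k = 2,
                       seed = 1)
  sr <- run_search(g, rules, ev, cfg)
  expect_true(all(vapply(sr$rounds, function(r) r$scored$total,
                         numeric(3)) == 0))
  expect_length(sr$rounds[[1]]$top_k, 0)
  expect_length(sr$consensus, 0)
})

test_that("consensus is the intersection of per-round top-k sets", {
  mk <- function(keys) list(top_k_keys = keys)
  r1 <- mk(c("A|B", "C|D", "E|F"))
  expect_equal(consensus_topk(list(r1)),
               list(c("A", "B"), c("C", "D"), c("E", "F")))
  expect_equal(consensus_topk(list(r1, r1)), consensus_topk(list(r1)))
  r2 <- mk(c("C|D", "X|Y"))
  expect_equal(consensus_topk(list(r1, r2)), list(c("C", "D")))
  r3 <- mk(character(0))
  expect_length(consensus_topk(list(r1, r3)), 0)
})

test_that("exhaustive enumeration covers C(n, x) and respects the cap", {
  b <- small_bundle(seed = 4, n_herbs = 6)
  ex <- exhaustive_ranking(b$graph, b$rules, b$evidence, x = 3)
  expect_equal(nrow(ex$ranking), choose(6, 3))
  expect_equal(length(ex$combos), 20)
  # same scoring as score_combination
  for (i in c(1, 7, 20)) {
    s <- score_combination(b$graph, ex$combos[[i]], b$rules, b$evidence)
    expect_equal(ex$ranking$total[i], s$total, tolerance = 1e-12)
  }
  expect_error(exhaustive_ranking(b$graph, b$rules, b$evidence, x = 3,
                                  cap = 10),
               "refusing to enumerate")
})

test_that("uniform-evidence, rule-free ranking is driven by diversity and hitting rates", {
  b <- small_bundle(seed = 12, n_herbs = 8)
  ev <- data.frame(herb_id = b$graph$herbs$id, c2 = 1, l = 10, j = 1, k = 1)
  ex <- exhaustive_ranking(b$graph, NULL, ev, x = 3)
  o <- vapply(ex$combos, function(cb) {
    r <- oracle_score(b$graph, cb, NULL, ev)
    r$g * r$triple_sum
  }, numeric(1))
  expect_equal(ex$ranking$total, o, tolerance = 1e-12)
  expect_true(!is.unsorted(rev(ex$ranking$total)))
})

test_that("round summaries are coherent with the score distribution", {
  b <- small_bundle(seed = 30)
  cfg <- search_config(x = 3, rounds = 2, combos_per_round = 50, top_k = 5,
                       seed = 2)
  sr <- run_search(b$graph, b$rules, b$evidence, cfg)
  for (r in sr$rounds) {
    expect_gte(r$summary$sd, 0)
    expect_gte(r$summary$mean, r$summary$min)
    expect_lte(r$summary$mean, r$summary$max)
    expect_equal(r$summary$mean, mean(r$scored$total))
  }
})

test_that("pooled ranking merges rounds, deduplicates and re-ranks", {
  b <- small_bundle(seed = 14, n_herbs = 6)
  cfg <- search_config(x = 3, rounds = 4, combos_per_round = 15, top_k = 3,
                       seed = 6)
  sr <- run_search(b$graph, b$rules, b$evidence, cfg)
  pool <- pooled_ranking(sr)
  expect_false(anyDuplicated(pool$key) > 0)
  expect_true(!is.unsorted(rev(pool$total)))
  expect_lte(nrow(pool), choose(6, 3))
  # pooled winner is at least as good as any per-round winner
  expect_equal(pool$total[1],
               max(vapply(sr$rounds, function(r) r$scored$total[1],
                          numeric(1))))
})
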