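worked_evidence <- data.frame(
  herb_id = c("A", "B"), c2 = c(1, 0), l = c(9, 0), j = c(1, 0), k = c(0, 0),
  stringsAsFactors = FALSE)

test_that("worked example: triples, diversity and total match hand computation", {
  g <- worked_example_graph()
  tr <- drug_score_triples(g, c("A", "B"), worked_evidence)
  expect_equal(tr$h1, c(0.2, 0.3))
  expect_equal(tr$h2, c(0.5, 0))
  expect_equal(tr$h3, c(log10(10), 0))  # l*(j+k)+1 = 9*1+1
  expect_equal(tr$norm, c(sqrt(0.2^2 + 0.5^2 + 1), 0.3))

  div <- target_diversity(g, c("A", "B"))  # T2 shared, t = 10
  expect_equal(div$w, 1)
  expect_equal(div$g, 0.9)

  s <- score_combination(g, c("A", "B"), rules = NULL,
                         evidence = worked_evidence)
  expect_equal(s$total, 0.9 * (sqrt(1.29) + 0.3), tolerance = 1e-12)
  expect_equal(s$total, 1.2922, tolerance = 1e-4)
})

test_that("penalty matches each rule kind exactly", {
  g <- toy_graph()  # HA: warm,sweet; HB: cold
  expect_equal(contraindication_penalty(g, c("HA", "HB"), NULL)$f, 1)

  hp <- data.frame(kind = "herb_pair", left = "HA", right = "HB", note = "")
  res <- contraindication_penalty(g, c("HA", "HB"), hp)
  expect_equal(res$f, 0)
  expect_equal(nrow(res$violated), 1)

  # attribute_pair with only one label present does not fire
  ap1 <- data.frame(kind = "attribute_pair", left = "warm", right = "missing_lab",
                    note = "")
  herbs2 <- g$herbs
  herbs2$attributes <- c("warm;sweet", "cold")
  g2 <- knowledge_graph(herbs2, g$targets, g$relations,
                        attribute_vocabulary = "missing_lab")
  expect_equal(contraindication_penalty(g2, c("HA", "HB"), ap1)$f, 1)

  ap2 <- data.frame(kind = "attribute_pair", left = "warm", right = "cold",
                    note = "")
  expect_equal(contraindication_penalty(g, c("HA", "HB"), ap2)$f, 0)

  # herb_attribute fires only when the attribute sits on a DIFFERENT member
  ha_other <- data.frame(kind = "herb_attribute", left = "HA", right = "cold",
                         note = "")
  expect_equal(contraindication_penalty(g, c("HA", "HB"), ha_other)$f, 0)
  ha_self <- data.frame(kind = "herb_attribute", left = "HA", right = "sweet",
                        note = "")
  expect_equal(contraindication_penalty(g, c("HA", "HB"), ha_self)$f, 1)

  bad <- data.frame(kind = "herb_pair", left = "HA", right = "NOPE", note = "")
  expect_error(contraindication_penalty(g, c("HA", "HB"), bad),
               "does not resolve")
})

test_that("diversity edge cases", {
  # disjoint target sets -> w = 0, g = 1
  g <- knowledge_graph(
    herbs = data.frame(id = c("H1", "H2"), name = c("a", "b")),
    targets = data.frame(id = paste0("T", 1:10), name = paste0("t", 1:10)),
    relations = data.frame(herb_id = c("H1", "H2"),
                           target_id = c("T1", "T2"),
                           ontology_term = "acts_on", provenance = ""))
  expect_equal(target_diversity(g, c("H1", "H2")), list(w = 0, g = 1))

  # all members hitting one identical target -> w = 1, g = 0.9
  g2 <- knowledge_graph(
    herbs = data.frame(id = c("H1", "H2", "H3"), name = c("a", "b", "c")),
    targets = data.frame(id = paste0("T", 1:10), name = paste0("t", 1:10)),
    relations = data.frame(herb_id = c("H1", "H2", "H3"), target_id = "T1",
                           ontology_term = "acts_on", provenance = ""))
  expect_equal(target_diversity(g2, c("H1", "H2", "H3")),
               list(w = 1, g = 0.9))

  g0 <- knowledge_graph(
    herbs = data.frame(id = c("H1", "H2"), name = c("a", "b")),
    targets = data.frame(id = character(), name = character()))
  expect_error(target_diversity(g0, c("H1", "H2")), "no targets")
})

test_that("zero evidence yields h3 = 0 under the +1 log guard", {
  g <- worked_example_graph()
  ev <- data.frame(herb_id = c("A", "B"), c2 = c(0, 0), l = c(0, 50),
                   j = c(1, 0), k = c(1, 0))
  tr <- drug_score_triples(g, c("A", "B"), ev)
  expect_equal(tr$h3, c(0, 0))  # l = 0; j = k = 0
})

test_that("missing evidence records default to zero with a warning", {
  g <- worked_example_graph()
  ev <- worked_evidence[1, , drop = FALSE]
  expect_warning(tr <- drug_score_triples(g, c("A", "B"), ev),
                 "no evidence record for herb\\(s\\) B")
  expect_equal(tr$h3[tr$herb_id == "B"], 0)
})

test_that("score is invariant under member ordering and rule violations zero it", {
  b <- random_toy_bundle(42)
  combo <- b$graph$herbs$id[1:3]
  s1 <- score_combination(b$graph, combo, b$rules, b$evidence)
  s2 <- score_combination(b$graph, rev(combo), b$rules, b$evidence)
  expect_identical(s1, s2)

  g <- toy_graph()
  hp <- data.frame(kind = "herb_pair", left = "HA", right = "HB", note = "")
  ev <- data.frame(herb_id = c("HA", "HB"), c2 = 1, l = 100, j = 1, k = 1)
  s <- score_combination(g, c("HA", "HB"), hp, ev)
  expect_equal(s$f, 0)
  expect_equal(s$total, 0)
  expect_gt(s$triple_sum, 0)
})

test_that("score matches the straight-from-the-formulas oracle on random toys", {
  for (seed in 1:100) {
    b <- random_toy_bundle(seed)
    x <- sample(2:min(4, nrow(b$graph$herbs)), 1)
    combo <- sample(b$graph$herbs$id, x)
    s <- score_combination(b$graph, combo, b$rules, b$evidence)
    o <- oracle_score(b$graph, combo, b$rules, b$evidence)
    expect_equal(s$f, o$f)
    expect_equal(s$w, o$w)
    expect_equal(s$g, o$g, tolerance = 1e-12)
    expect_equal(s$triple_sum, o$triple_sum, tolerance = 1e-12)
    expect_equal(s$total, o$total, tolerance = 1e-12)
    # range invariants
    expect_true(s$g >= 0 && s$g <= 1)
    expect_true(all(s$triples$h1 >= 0 & s$triples$h1 <= 1))
    expect_true(all(s$triples$h2 %in% c(0, 1 / x)))
    expect_true(all(s$triples$h3 >= 0))
    expect_gte(s$total, 0)
  }
})

test_that("adding a disjoint member keeps w and cannot decrease the norm sum", {
  # h2 = c2/x rescales with combination size, so the norm-sum monotonicity
  # holds for phenotype-free evidence (c2 = 0), where per-herb norms do not
  # depend on x; w-invariance holds regardless
  for (seed in 1:20) {
    b <- random_toy_bundle(seed + 300)
    g <- b$graph
    ev <- b$evidence
    ev$c2 <- 0
    ids <- g$herbs$id
    base <- sample(ids, 2)
    cand <- setdiff(ids, base)
    disjoint <- cand[vapply(cand, function(h)
      length(intersect(kg_targets_of(g, h),
                       unlist(lapply(base, kg_targets_of, graph = g)))) == 0,
      logical(1))]
    s0_full <- score_combination(g, base, NULL, b$evidence)
    s0 <- score_combination(g, base, NULL, ev)
    if (!length(disjoint)) next
    s1_full <- score_combination(g, c(base, disjoint[1]), NULL, b$evidence)
    s1 <- score_combination(g, c(base, disjoint[1]), NULL, ev)
    expect_equal(s1_full$w, s0_full$w)
    expect_equal(s1$w, s0$w)
    expect_gte(s1$triple_sum + 1e-12, s0$triple_sum)
  }
})

test_that("L1 norm option aggregates as the component sum", {
  g <- worked_example_graph()
  tr <- drug_score_triples(g, c("A", "B"), worked_evidence, norm = "l1")
  expect_equal(tr$norm, tr$h1 + tr$h2 + tr$h3)
})
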