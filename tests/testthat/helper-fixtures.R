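# Shared fixtures and independent oracles. The oracles recompute quantities
# straight from their definitions (plain loops over the relation table), not
# through the package's adjacency/engine code paths.

toy_graph <- function() {
  knowledge_graph(
    herbs = data.frame(id = c("HA", "HB"),
                       name = c("herb A", "herb B"),
                       attributes = c("warm;sweet", "cold"),
                       stringsAsFactors = FALSE),
    targets = data.frame(id = paste0("T", 1:3),
                         name = paste("target", 1:3),
                         stringsAsFactors = FALSE),
    relations = data.frame(
      herb_id = c("HA", "HA", "HB", "HB"),
      target_id = c("T1", "T2", "T2", "T3"),
      ontology_term = c("activates", "inhibits", "activates", "binds"),
      provenance = "toy", stringsAsFactors = FALSE))
}

# 10-target graph matching the worked scoring example: A hits 2 targets,
# B hits 3, sharing exactly one
worked_example_graph <- function() {
  knowledge_graph(
    herbs = data.frame(id = c("A", "B"), name = c("a", "b"),
                       attributes = "", stringsAsFactors = FALSE),
    targets = data.frame(id = paste0("T", 1:10), name = paste0("t", 1:10),
                         stringsAsFactors = FALSE),
    relations = data.frame(
      herb_id = c("A", "A", "B", "B", "B"),
      target_id = c("T1", "T2", "T2", "T3", "T4"),
      ontology_term = "acts_on", provenance = "toy",
      stringsAsFactors = FALSE))
}

random_toy_bundle <- function(seed) {
  set.seed(seed)
  n_herbs <- sample(4:8, 1)
  n_targets <- sample(5:12, 1)
  n_edges <- sample(n_herbs:min(2 * n_herbs * 3, n_herbs * n_targets), 1)
  cfg <- kg_sim_config(
    n_herbs = n_herbs, n_targets = n_targets, n_auxiliary = 0,
    n_herb_target_edges = n_edges, n_auxiliary_edges = 0,
    n_attributes = 6, n_ontology_terms = 3,
    concentration = stats::runif(1, 0, 2),
    n_herb_pair_rules = sample(0:2, 1),
    n_attribute_pair_rules = sample(0:2, 1),
    n_pathways = 0)
  simulate_kg(cfg, seed = seed + 1)
}

# straight-from-the-definitions score recomputation
oracle_score <- function(graph, combo, rules, evidence, norm = "l2") {
  combo <- sort(as.character(combo))
  x <- length(combo)
  t_total <- nrow(graph$targets)
  pooled <- unique(unlist(lapply(combo, function(h) graph$attributes[[h]])))
  f <- 1
  if (!is.null(rules) && nrow(rules)) {
    for (i in seq_len(nrow(rules))) {
      hit <- switch(rules$kind[i],
        herb_pair = rules$left[i] %in% combo && rules$right[i] %in% combo,
        attribute_pair = rules$left[i] %in% pooled &&
          rules$right[i] %in% pooled,
        herb_attribute = {
          others <- setdiff(combo, rules$left[i])
          oat <- unique(unlist(lapply(others,
                                      function(h) graph$attributes[[h]])))
          rules$left[i] %in% combo && rules$right[i] %in% oat
        })
      if (isTRUE(hit)) f <- 0
    }
  }
  tsets <- lapply(combo, function(h)
    unique(graph$relations$target_id[graph$relations$herb_id == h]))
  all_t <- unique(unlist(tsets))
  w <- 0
  for (tg in all_t) {
    hitters <- sum(vapply(tsets, function(s) tg %in% s, logical(1)))
    if (hitters >= 2) w <- w + 1
  }
  g <- 1 - w / t_total
  triple_sum <- 0
  for (i in seq_along(combo)) {
    h <- combo[i]
    row <- evidence[evidence$herb_id == h, , drop = FALSE]
    c2 <- if (nrow(row)) row$c2 else 0
    l <- if (nrow(row)) row$l else 0
    jj <- if (nrow(row)) row$j else 0
    kk <- if (nrow(row)) row$k else 0
    h1 <- length(tsets[[i]]) / t_total
    h2 <- c2 * (1 / x)
    h3 <- 1 * log10(l * (jj + kk) + 1)
    triple_sum <- triple_sum +
      if (norm == "l2") sqrt(h1^2 + h2^2 + h3^2) else h1 + h2 + h3
  }
  list(f = f, w = w, g = g, triple_sum = triple_sum,
       total = f * g * triple_sum)
}

# exact hypergeometric upper tail by combinatorial enumeration
oracle_hyper_upper <- function(N, K, n, k) {
  ks <- seq(max(0, k), min(K, n))
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

write_toy_tables <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  nodes <- c(
    "#! attribute declared_extra",
    "id\tnode_type\tname\tattributes",
    "HA\therb\therb A\twarm;sweet",
    "HB\therb\therb B\tcold",
    "T1\ttarget\ttarget 1\t",
    "T2\ttarget\ttarget 2\t",
    "T3\ttarget\ttarget 3\t")
  edges <- c(
    "source\ttarget\tontology_term\tprovenance",
    "HA\tT1\tactivates\ttoy",
    "HA\tT2\tinhibits\ttoy",
    "HB\tT2\tactivates\ttoy",
    "HB\tT3\tbinds\ttoy")
  np <- file.path(dir, "nodes.tsv")
  ep <- file.path(dir, "edges.tsv")
  writeLines(nodes, np)
  writeLines(edges, ep)
  list(nodes = np, edges = ep, dir = dir)
}
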