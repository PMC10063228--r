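# Seeded generator of synthetic knowledge graphs, evidence tables,
# contraindication rules and pathway sets at the published graph's scale
# (345 herbs, 240 targets, 64 attribute labels, 13 ontology terms, 895
# materialized nodes, 2197 edges), so every component is testable without
# external data. The generated content is synthetic throughout: it emulates
# scale and schema, not the real graph's biology.

#' Generator configuration
#'
#' Defaults reproduce the published graph's scale exactly: 345 herbs + 240
#' targets + 233 auxiliary phenotype/disease/evidence nodes + 64 attribute
#' labels + 13 ontology terms = 895 materialized nodes, and 1600 herb-target
#' relations + 597 auxiliary edges = 2197 edges.
#'
#' @param n_herbs,n_targets,n_auxiliary node counts.
#' @param n_herb_target_edges,n_auxiliary_edges edge budget split.
#' @param n_attributes,n_ontology_terms vocabulary sizes.
#' @param concentration herb degree concentration; 0 gives uniform edge
#'   assignment, larger values give heavier-tailed herb degrees (gamma-weight
#'   multinomial with weight variance equal to `concentration`).
#' @param attrs_per_herb integer range (min, max) of attribute labels per herb.
#' @param phenotype_positive probability a herb has `c2 = 1`.
#' @param publication_mean mean of the geometric publication-count
#'   distribution.
#' @param p_cellline,p_tissue probabilities of the `j` and `k` validation
#'   flags.
#' @param n_herb_pair_rules,n_attribute_pair_rules contraindication rule
#'   counts.
#' @param n_pathways,pathway_size pathway-set count and integer size range.
#' @return A `kg_sim_config` list.
#' @export
kg_sim_config <- function(n_herbs = 345, n_targets = 240, n_auxiliary = 233,
                          n_herb_target_edges = 1600, n_auxiliary_edges = 597,
                          n_attributes = 64, n_ontology_terms = 13,
                          concentration = 0.5, attrs_per_herb = c(1, 4),
                          phenotype_positive = 0.3, publication_mean = 3,
                          p_cellline = 0.4, p_tissue = 0.3,
                          n_herb_pair_rules = 8, n_attribute_pair_rules = 4,
                          n_pathways = 20, pathway_size = c(5, 30)) {
  cfg <- list(n_herbs = n_herbs, n_targets = n_targets,
              n_auxiliary = n_auxiliary,
              n_herb_target_edges = n_herb_target_edges,
              n_auxiliary_edges = n_auxiliary_edges,
              n_attributes = n_attributes,
              n_ontology_terms = n_ontology_terms,
              concentration = concentration,
              attrs_per_herb = attrs_per_herb,
              phenotype_positive = phenotype_positive,
              publication_mean = publication_mean,
              p_cellline = p_cellline, p_tissue = p_tissue,
              n_herb_pair_rules = n_herb_pair_rules,
              n_attribute_pair_rules = n_attribute_pair_rules,
              n_pathways = n_pathways, pathway_size = pathway_size)
  counts <- unlist(cfg[c("n_herbs", "n_targets", "n_auxiliary",
                         "n_herb_target_edges", "n_auxiliary_edges",
                         "n_attributes", "n_ontology_terms")])
  if (any(counts < 0)) stop("all counts must be non-negative")
  if (n_herb_target_edges > n_herbs * n_targets)
    stop("n_herb_target_edges exceeds the number of possible herb-target pairs")
  if (n_auxiliary_edges > 0 && n_auxiliary == 0)
    stop("auxiliary edges require auxiliary nodes")
  if (cfg$concentration < 0) stop("concentration must be >= 0")
  structure(cfg, class = "kg_sim_config")
}

.pad_id <- function(prefix, i, n) sprintf("%s%0*d", prefix, nchar(n), i)

#' Generate a synthetic knowledge-graph bundle
#'
#' Produces a graph (herb degrees drawn from a concentration-controlled
#' multinomial over gamma herb weights, attributes per herb from the
#' attribute vocabulary, ontology terms per edge from the relation
#' vocabulary), a per-herb evidence table (Bernoulli phenotype flag,
#' geometric publication counts, Bernoulli validation flags), herb-pair and
#' attribute-pair contraindication rules, and random pathway sets over the
#' target universe. Fully reproducible from `seed`.
#'
#' @param config a [kg_sim_config()].
#' @param seed integer RNG seed.
#' @return An object of class `kg_bundle`: list with `graph`, `evidence`,
#'   `rules`, `pathways`, `planted` (NULL until [plant_combination()]),
#'   `config`, `seed`.
#' @export
simulate_kg <- function(config = kg_sim_config(), seed = 1) {
  stopifnot(inherits(config, "kg_sim_config"))
  set.seed(seed)
  H <- config$n_herbs; T_ <- config$n_targets; A <- config$n_auxiliary
  herb_ids <- .pad_id("H", seq_len(H), H)
  target_ids <- .pad_id("T", seq_len(T_), T_)
  aux_ids <- if (A > 0) .pad_id("X", seq_len(A), A) else character()
  attr_vocab <- .pad_id("attr", seq_len(config$n_attributes),
                        config$n_attributes)
  ont_vocab <- .pad_id("rel", seq_len(config$n_ontology_terms),
                       config$n_ontology_terms)

  # herb degrees: gamma weights (mean 1, variance = concentration) feeding a
  # multinomial; concentration -> 0 recovers uniform edge assignment
  E <- config$n_herb_target_edges
  if (config$concentration > 0) {
    shape <- 1 / config$concentration
    w <- stats::rgamma(H, shape = shape, rate = shape)
    w <- pmax(w, .Machine$double.eps)
  } else {
    w <- rep(1, H)
  }
  deg <- as.integer(stats::rmultinom(1, E, prob = w))
  # cap at the target-universe size, pushing overflow onto other herbs
  over <- sum(pmax(deg - T_, 0L))
  deg <- pmin(deg, T_)
  while (over > 0) {
    room <- which(deg < T_)
    take <- utils::head(room[order(stats::runif(length(room)))], over)
    deg[take] <- deg[take] + 1L
    over <- over - length(take)
  }
  rel_herb <- rep(herb_ids, deg)
  rel_target <- unlist(lapply(deg, function(d)
    if (d > 0) target_ids[sample.int(T_, d)] else character()),
    use.names = FALSE)
  relations <- data.frame(
    herb_id = rel_herb, target_id = rel_target,
    ontology_term = ont_vocab[sample.int(length(ont_vocab),
                                         length(rel_herb), replace = TRUE)],
    provenance = "synthetic", stringsAsFactors = FALSE)

  n_attrs <- sample(config$attrs_per_herb[1]:config$attrs_per_herb[2], H,
                    replace = TRUE)
  attrs <- lapply(n_attrs, function(m)
    attr_vocab[sample.int(length(attr_vocab), m)])
  herbs <- data.frame(id = herb_ids,
                      name = paste("herb", seq_len(H)),
                      stringsAsFactors = FALSE)
  herbs$attributes <- I(attrs)
  targets <- data.frame(id = target_ids,
                        name = paste("target", seq_len(T_)),
                        stringsAsFactors = FALSE)
  auxiliary <- data.frame(id = aux_ids,
                          name = if (A > 0) paste("auxiliary", seq_len(A))
                                 else character(),
                          stringsAsFactors = FALSE)

  aux_edges <- NULL
  if (config$n_auxiliary_edges > 0) {
    nA <- config$n_auxiliary_edges
    # every auxiliary node gets at least one edge where the budget allows
    src <- c(aux_ids[seq_len(min(A, nA))],
             if (nA > A) aux_ids[sample.int(A, nA - A, replace = TRUE)])
    primary <- c(herb_ids, target_ids)
    dst <- primary[sample.int(length(primary), nA, replace = TRUE)]
    aux_edges <- data.frame(
      source = src, target = dst,
      ontology_term = ont_vocab[sample.int(length(ont_vocab), nA,
                                           replace = TRUE)],
      provenance = "synthetic", stringsAsFactors = FALSE)
    aux_edges <- unique(aux_edges)
    # resample collisions so the edge budget is met exactly
    tries <- 0L
    while (nrow(aux_edges) < nA && tries < 1000L) {
      tries <- tries + 1L
      need <- nA - nrow(aux_edges)
      extra <- data.frame(
        source = aux_ids[sample.int(A, need, replace = TRUE)],
        target = primary[sample.int(length(primary), need, replace = TRUE)],
        ontology_term = ont_vocab[sample.int(length(ont_vocab), need,
                                             replace = TRUE)],
        provenance = "synthetic", stringsAsFactors = FALSE)
      aux_edges <- unique(rbind(aux_edges, extra))
    }
  }

  graph <- knowledge_graph(herbs = herbs, targets = targets,
                           relations = unique(relations),
                           auxiliary = auxiliary, aux_edges = aux_edges,
                           attribute_vocabulary = attr_vocab,
                           ontology_vocabulary = ont_vocab)

  geom_p <- 1 / (1 + config$publication_mean)
  evidence <- data.frame(
    herb_id = herb_ids,
    c2 = stats::rbinom(H, 1, config$phenotype_positive),
    l = stats::rgeom(H, geom_p),
    j = stats::rbinom(H, 1, config$p_cellline),
    k = stats::rbinom(H, 1, config$p_tissue),
    stringsAsFactors = FALSE)

  rules <- .simulate_rules(herb_ids, attr_vocab,
                           config$n_herb_pair_rules,
                           config$n_attribute_pair_rules)
  pathways <- .simulate_pathways(target_ids, config$n_pathways,
                                 config$pathway_size)
  structure(list(graph = graph, evidence = evidence, rules = rules,
                 pathways = pathways, planted = NULL, config = config,
                 seed = seed), class = "kg_bundle")
}

.simulate_rules <- function(herb_ids, attr_vocab, n_herb_pair, n_attr_pair) {
  hp <- if (n_herb_pair > 0) {
    pairs <- t(replicate(n_herb_pair, sample(herb_ids, 2)))
    data.frame(kind = "herb_pair", left = pairs[, 1], right = pairs[, 2],
               note = "synthetic incompatibility", stringsAsFactors = FALSE)
  }
  ap <- if (n_attr_pair > 0) {
    pairs <- t(replicate(n_attr_pair, sample(attr_vocab, 2)))
    data.frame(kind = "attribute_pair", left = pairs[, 1], right = pairs[, 2],
               note = "synthetic incompatibility", stringsAsFactors = FALSE)
  }
  out <- rbind(hp, ap)
  if (is.null(out))
    out <- data.frame(kind = character(), left = character(),
                      right = character(), note = character(),
                      stringsAsFactors = FALSE)
  out
}

.simulate_pathways <- function(target_ids, n_pathways, size_range) {
  if (n_pathways == 0) return(list())
  out <- lapply(seq_len(n_pathways), function(i) {
    sz <- sample(size_range[1]:size_range[2], 1)
    sz <- min(sz, length(target_ids))
    list(name = sprintf("PATHWAY_%03d", i),
         description = "synthetic pathway set",
         members = sort(target_ids[sample.int(length(target_ids), sz)]))
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Plant a high-scoring combination into a bundle
#'
#' Designates `x` herbs and rewires their relations so the union of their
#' target sets has exactly `joint_target_count` members split as evenly as
#' possible with no pairwise overlap (maximal target diversity), boosts their
#' evidence (`c2 = 1`, large publication count, both validation flags), and
#' removes any rule conflict: rules naming a planted herb are dropped and
#' planted herbs' attributes are reassigned to labels unused by
#' attribute-pair rules. The rest of the graph is untouched except the
#' rewired edges.
#'
#' @param bundle a `kg_bundle`.
#' @param x number of planted herbs.
#' @param joint_target_count exact size of the planted joint target set.
#' @param seed RNG seed for the planting choices (defaults to the bundle
#'   seed + 1).
#' @param publication_count evidence `l` for planted herbs.
#' @return The modified bundle; `bundle$planted` holds `combination`,
#'   `joint_target_count`, `targets`.
#' @export
plant_combination <- function(bundle, x = 8, joint_target_count = 46,
                              seed = NULL, publication_count = 500) {
  stopifnot(inherits(bundle, "kg_bundle"))
  g <- bundle$graph
  if (x > nrow(g$herbs)) stop("x exceeds the number of herbs")
  if (joint_target_count > nrow(g$targets))
    stop("joint_target_count exceeds the number of targets")
  if (joint_target_count < x)
    stop("need at least one target per planted herb")
  if (is.null(seed)) seed <- bundle$seed + 1L
  set.seed(seed)

  members <- sort(sample(g$herbs$id, x))
  planted_targets <- sort(sample(g$targets$id, joint_target_count))
  sizes <- rep(joint_target_count %/% x, x)
  extra <- joint_target_count %% x
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  assign_idx <- rep(seq_len(x), sizes)

  ont <- g$ontology_vocabulary
  new_rel <- data.frame(
    herb_id = members[assign_idx],
    target_id = planted_targets,
    ontology_term = ont[sample.int(length(ont), joint_target_count,
                                   replace = TRUE)],
    provenance = "synthetic planted", stringsAsFactors = FALSE)
  relations <- rbind(
    g$relations[!g$relations$herb_id %in% members, , drop = FALSE],
    new_rel)

  # attributes safe under every attribute_pair rule
  rules <- bundle$rules
  rules <- rules[!(rules$kind %in% c("herb_pair", "herb_attribute") &
                     (rules$left %in% members | rules$right %in% members)), ,
                 drop = FALSE]
  unsafe <- unique(c(rules$left[rules$kind == "attribute_pair"],
                     rules$right[rules$kind == "attribute_pair"]))
  safe <- setdiff(g$attribute_vocabulary, unsafe)
  if (!length(safe)) stop("no attribute label is free of attribute_pair rules")
  attrs <- g$attributes
  for (m in members)
    attrs[[m]] <- sort(safe[sample.int(length(safe),
                                       min(2, length(safe)))])

  herbs <- g$herbs
  herbs$attributes <- I(unname(attrs[herbs$id]))
  bundle$graph <- knowledge_graph(
    herbs = herbs, targets = g$targets, relations = relations,
    auxiliary = g$auxiliary, aux_edges = g$aux_edges,
    attribute_vocabulary = g$attribute_vocabulary,
    ontology_vocabulary = g$ontology_vocabulary)

  ev <- bundle$evidence
  sel <- ev$herb_id %in% members
  ev$c2[sel] <- 1
  ev$l[sel] <- publication_count
  ev$j[sel] <- 1
  ev$k[sel] <- 1
  bundle$evidence <- ev
  bundle$rules <- rules
  bundle$planted <- list(combination = members,
                         joint_target_count = joint_target_count,
                         targets = planted_targets)
  bundle
}

#' Write a bundle's tables to a directory
#'
#' Writes `nodes.tsv`, `edges.tsv`, `evidence.tsv`, `rules.tsv`,
#' `pathways.gmt` and a `manifest.json` recording the configuration, seed and
#' any planted combination.
#'
#' @param bundle a `kg_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "kg_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kg_write_tables(bundle$graph, file.path(dir, "nodes.tsv"),
                  file.path(dir, "edges.tsv"))
  utils::write.table(bundle$evidence, file.path(dir, "evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$rules, file.path(dir, "rules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(bundle$pathways))
    write_gmt(bundle$pathways, file.path(dir, "pathways.gmt"))
  manifest <- list(seed = bundle$seed,
                   config = unclass(bundle$config),
                   planted = bundle$planted,
                   stats = kg_stats(bundle$graph))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
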