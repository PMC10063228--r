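#' @keywords internal
"_PACKAGE"

# Typed in-memory knowledge graph over herbal drug entities and cellular
# targets. Herbs carry medicinal-attribute labels; herb->target relations
# carry one of the graph's relation-ontology terms. Attributes and ontology
# terms are stored as labels, not graph nodes; node-total bookkeeping can
# optionally count them as materialized nodes (see kg_stats).

#' Construct a validated knowledge graph
#'
#' Builds the package's central container: herb nodes with medicinal-attribute
#' labels, target nodes, typed herb-to-target relations, and optional
#' auxiliary nodes (phenotype/disease/evidence bookkeeping) with their edges.
#'
#' @param herbs data.frame with columns `id`, `name` and either a list column
#'   `attributes` (character vectors of medicinal-attribute labels) or a
#'   character column of semicolon-separated labels.
#' @param targets data.frame with columns `id`, `name`.
#' @param relations data.frame with columns `herb_id`, `target_id`,
#'   `ontology_term`, `provenance`; may be `NULL` for an edgeless graph.
#' @param auxiliary optional data.frame of auxiliary nodes (`id`, `name`).
#' @param aux_edges optional data.frame of edges touching auxiliary nodes
#'   (`source`, `target`, `ontology_term`, `provenance`).
#' @param attribute_vocabulary,ontology_vocabulary optional character vectors
#'   declaring the full label vocabularies; the observed labels are always
#'   included.
#' @return An object of class `herb_kg`.
#' @examples
#' g <- knowledge_graph(
#'   herbs = data.frame(id = c("H1", "H2"), name = c("herb one", "herb two"),
#'                      attributes = c("warm;sweet", "cold")),
#'   targets = data.frame(id = c("T1", "T2"), name = c("t1", "t2")),
#'   relations = data.frame(herb_id = "H1", target_id = "T1",
#'                          ontology_term = "activates", provenance = "toy"))
#' kg_stats(g)
#' @export
knowledge_graph <- function(herbs, targets, relations = NULL, auxiliary = NULL,
                            aux_edges = NULL, attribute_vocabulary = NULL,
                            ontology_vocabulary = NULL) {
  herbs <- as.data.frame(herbs, stringsAsFactors = FALSE)
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name") %in% names(herbs)),
            all(c("id", "name") %in% names(targets)))
  herbs$id <- trimws(as.character(herbs$id))
  targets$id <- trimws(as.character(targets$id))

  if (anyDuplicated(herbs$id))
    stop("duplicate herb id(s): ",
         paste(unique(herbs$id[duplicated(herbs$id)]), collapse = ", "))
  if (anyDuplicated(targets$id))
    stop("duplicate target id(s): ",
         paste(unique(targets$id[duplicated(targets$id)]), collapse = ", "))

  attrs <- .parse_attributes(herbs)
  herbs <- herbs[c("id", "name")]

  if (is.null(auxiliary))
    auxiliary <- data.frame(id = character(), name = character(),
                            stringsAsFactors = FALSE)
  auxiliary <- as.data.frame(auxiliary, stringsAsFactors = FALSE)
  auxiliary$id <- trimws(as.character(auxiliary$id))
  all_ids <- c(herbs$id, targets$id, auxiliary$id)
  if (anyDuplicated(all_ids))
    stop("node id(s) not unique across herb/target/auxiliary sets: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))

  if (is.null(relations))
    relations <- data.frame(herb_id = character(), target_id = character(),
                            ontology_term = character(), provenance = character(),
                            stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (!"provenance" %in% names(relations)) relations$provenance <- ""
  relations <- relations[c("herb_id", "target_id", "ontology_term", "provenance")]
  for (cn in names(relations)) relations[[cn]] <- trimws(as.character(relations[[cn]]))

  bad <- which(!(relations$herb_id %in% herbs$id))
  if (length(bad))
    stop("relation row ", bad[1], " references unknown herb id '",
         relations$herb_id[bad[1]], "'")
  bad <- which(!(relations$target_id %in% targets$id))
  if (length(bad))
    stop("relation row ", bad[1], " references unknown target id '",
         relations$target_id[bad[1]], "'")
  key <- paste(relations$herb_id, relations$target_id, relations$ontology_term,
               sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate relation (herb_id, target_id, ontology_term) at row ",
         which(duplicated(key))[1])

  if (is.null(aux_edges))
    aux_edges <- data.frame(source = character(), target = character(),
                            ontology_term = character(), provenance = character(),
                            stringsAsFactors = FALSE)
  aux_edges <- as.data.frame(aux_edges, stringsAsFactors = FALSE)
  if (!"provenance" %in% names(aux_edges)) aux_edges$provenance <- ""
  aux_edges <- aux_edges[c("source", "target", "ontology_term", "provenance")]
  for (cn in names(aux_edges)) aux_edges[[cn]] <- trimws(as.character(aux_edges[[cn]]))
  bad <- which(!(aux_edges$source %in% all_ids) | !(aux_edges$target %in% all_ids))
  if (length(bad))
    stop("auxiliary edge row ", bad[1], " has a dangling endpoint ('",
         aux_edges$source[bad[1]], "' -> '", aux_edges$target[bad[1]], "')")
  touches_aux <- aux_edges$source %in% auxiliary$id |
    aux_edges$target %in% auxiliary$id
  if (any(!touches_aux))
    stop("auxiliary edge row ", which(!touches_aux)[1],
         " joins two primary nodes; herb->target edges belong in `relations`")

  attribute_vocabulary <- sort(unique(c(
    as.character(attribute_vocabulary), unlist(attrs, use.names = FALSE))))
  ontology_vocabulary <- sort(unique(c(
    as.character(ontology_vocabulary), relations$ontology_term,
    aux_edges$ontology_term)))

  g <- structure(list(
    herbs = herbs, targets = targets, relations = relations,
    auxiliary = auxiliary, aux_edges = aux_edges,
    attributes = attrs,
    attribute_vocabulary = attribute_vocabulary,
    ontology_vocabulary = ontology_vocabulary), class = "herb_kg")
  g$adjacency <- .build_adjacency(g)
  g
}

.parse_attributes <- function(herbs) {
  if ("attributes" %in% names(herbs)) {
    a <- herbs$attributes
    if (is.list(a)) {
      attrs <- lapply(a, function(v) sort(unique(trimws(as.character(v)))))
    } else {
      attrs <- lapply(strsplit(ifelse(is.na(a), "", as.character(a)), ";",
                               fixed = TRUE),
                      function(v) sort(unique(trimws(v[nzchar(trimws(v))]))))
    }
  } else {
    attrs <- rep(list(character()), nrow(herbs))
  }
  names(attrs) <- herbs$id
  attrs
}

# herb id -> sorted integer indices into targets$id (multigraph relations
# collapse to one logical link; scoring counts targets, not edges)
.build_adjacency <- function(g) {
  idx <- match(g$relations$target_id, g$targets$id)
  by_herb <- split(idx, factor(g$relations$herb_id, levels = g$herbs$id))
  lapply(by_herb, function(v) sort(unique(v)))
}

#' Load a knowledge graph from node and edge tables
#'
#' Reads UTF-8 tab-separated tables. Lines starting with `#` are comments;
#' lines of the form `#! attribute <label>` or `#! ontology <term>` declare
#' vocabulary entries beyond those observed in the data. The node table needs
#' columns `id`, `node_type` (one of herb/target/auxiliary), `name`,
#' `attributes` (semicolon-separated, herbs only); the edge table needs
#' `source`, `target`, `ontology_term`, `provenance`.
#'
#' @param node_table,edge_table paths to the TSV files.
#' @return A validated `herb_kg`.
#' @export
kg_load <- function(node_table, edge_table) {
  for (p in c(node_table, edge_table))
    if (!file.exists(p)) stop("file not found: ", p)
  nodes <- .read_tsv(node_table)
  edges <- .read_tsv(edge_table)
  need <- c("id", "node_type", "name")
  if (!all(need %in% names(nodes)))
    stop("node table must have columns id, node_type, name")
  if (!all(c("source", "target", "ontology_term") %in% names(edges)))
    stop("edge table must have columns source, target, ontology_term")
  bad <- which(!nodes$node_type %in% c("herb", "target", "auxiliary"))
  if (length(bad))
    stop("node row ", bad[1], " has unknown node_type '", nodes$node_type[bad[1]], "'")

  bad <- which(!(edges$source %in% nodes$id))
  if (length(bad))
    stop("edge row ", bad[1], " references unknown node id '",
         edges$source[bad[1]], "'")
  bad <- which(!(edges$target %in% nodes$id))
  if (length(bad))
    stop("edge row ", bad[1], " references unknown node id '",
         edges$target[bad[1]], "'")

  vocab <- c(.read_vocab_block(node_table), .read_vocab_block(edge_table))
  herbs <- nodes[nodes$node_type == "herb", , drop = FALSE]
  targets <- nodes[nodes$node_type == "target", c("id", "name"), drop = FALSE]
  auxiliary <- nodes[nodes$node_type == "auxiliary", c("id", "name"), drop = FALSE]

  is_rel <- edges$source %in% herbs$id & edges$target %in% targets$id
  relations <- edges[is_rel, , drop = FALSE]
  names(relations)[names(relations) == "source"] <- "herb_id"
  names(relations)[names(relations) == "target"] <- "target_id"
  knowledge_graph(
    herbs = herbs, targets = targets, relations = relations,
    auxiliary = auxiliary, aux_edges = edges[!is_rel, , drop = FALSE],
    attribute_vocabulary = vocab$attribute,
    ontology_vocabulary = vocab$ontology)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8", check.names = TRUE)
}

.read_vocab_block <- function(path) {
  ln <- readLines(path, encoding = "UTF-8", warn = FALSE)
  decl <- ln[startsWith(ln, "#!")]
  out <- list(attribute = character(), ontology = character())
  for (d in decl) {
    parts <- strsplit(trimws(sub("^#!", "", d)), "\\s+")[[1]]
    if (length(parts) >= 2 && parts[1] %in% names(out))
      out[[parts[1]]] <- c(out[[parts[1]]],
                           paste(parts[-1], collapse = " "))
  }
  out
}

#' Targets adjacent to a herb
#'
#' Returns the distinct target ids linked to a herb by any relation; multiple
#' relations with different ontology terms collapse to a single logical link.
#'
#' @param graph a `herb_kg`.
#' @param herb_id a single herb id.
#' @return Sorted character vector of target ids (possibly empty).
#' @export
kg_targets_of <- function(graph, herb_id) {
  stopifnot(inherits(graph, "herb_kg"))
  if (!herb_id %in% graph$herbs$id) stop("unknown herb id '", herb_id, "'")
  graph$targets$id[graph$adjacency[[herb_id]]]
}

#' Summary counts of a knowledge graph
#'
#' By default, total nodes follow the materialized bookkeeping convention in
#' which each medicinal-attribute label and relation-ontology term counts as a
#' node (reproducing property-graph-database totals); `materialize_vocab =
#' FALSE` counts only herb, target and auxiliary nodes.
#'
#' @param graph a `herb_kg`.
#' @param materialize_vocab logical; count vocabulary labels as nodes.
#' @return Named list: `nodes`, `edges`, `herbs`, `targets`, `auxiliary`,
#'   `attributes`, `ontology_terms`, `primary_nodes`.
#' @export
kg_stats <- function(graph, materialize_vocab = TRUE) {
  stopifnot(inherits(graph, "herb_kg"))
  primary <- nrow(graph$herbs) + nrow(graph$targets) + nrow(graph$auxiliary)
  vocab_n <- length(graph$attribute_vocabulary) + length(graph$ontology_vocabulary)
  list(
    nodes = primary + if (materialize_vocab) vocab_n else 0L,
    edges = nrow(graph$relations) + nrow(graph$aux_edges),
    herbs = nrow(graph$herbs),
    targets = nrow(graph$targets),
    auxiliary = nrow(graph$auxiliary),
    attributes = length(graph$attribute_vocabulary),
    ontology_terms = length(graph$ontology_vocabulary),
    primary_nodes = primary)
}

#' @export
print.herb_kg <- function(x, ...) {
  s <- kg_stats(x)
  cat("<herb_kg> ", s$herbs, " herbs, ", s$targets, " targets, ",
      s$auxiliary, " auxiliary nodes; ", s$edges, " edges (",
      nrow(x$relations), " herb-target relations); ",
      s$attributes, " attribute labels, ", s$ontology_terms,
      " ontology terms\n", sep = "")
  invisible(x)
}

#' Export a knowledge graph to GraphML or node-link JSON
#'
#' GraphML output (via igraph) is loadable by standard network-visualization
#' tools such as Cytoscape; node type, name and semicolon-joined attributes
#' travel as node data and the ontology term as edge data. JSON output is a
#' node-link document that [kg_import_json()] reads back losslessly.
#'
#' @param graph a `herb_kg`.
#' @param format `"graphml"` or `"json"`.
#' @param out output file path.
#' @param materialize_vocab logical; for GraphML only, additionally emit each
#'   attribute label and ontology term as its own node with membership edges
#'   (property-graph-style totals).
#' @return `out`, invisibly.
#' @export
kg_export <- function(graph, format = c("graphml", "json"), out,
                      materialize_vocab = FALSE) {
  stopifnot(inherits(graph, "herb_kg"))
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      directed = TRUE,
      nodes = rbind(
        data.frame(id = graph$herbs$id, node_type = "herb",
                   name = graph$herbs$name,
                   attributes = vapply(graph$attributes, paste,
                                       character(1), collapse = ";"),
                   stringsAsFactors = FALSE),
        data.frame(id = graph$targets$id, node_type = "target",
                   name = graph$targets$name, attributes = "",
                   stringsAsFactors = FALSE),
        if (nrow(graph$auxiliary))
          data.frame(id = graph$auxiliary$id, node_type = "auxiliary",
                     name = graph$auxiliary$name, attributes = "",
                     stringsAsFactors = FALSE)),
      links = rbind(
        stats::setNames(graph$relations, c("source", "target", "ontology_term",
                                           "provenance")),
        graph$aux_edges),
      attribute_vocabulary = graph$attribute_vocabulary,
      ontology_vocabulary = graph$ontology_vocabulary)
    jsonlite::write_json(doc, out, auto_unbox = TRUE, digits = NA,
                         pretty = FALSE)
    return(invisible(out))
  }
  ig <- .as_igraph(graph, materialize_vocab = materialize_vocab)
  igraph::write_graph(ig, out, format = "graphml")
  invisible(out)
}

.as_igraph <- function(graph, materialize_vocab = FALSE) {
  nodes <- data.frame(
    name = c(graph$herbs$id, graph$targets$id, graph$auxiliary$id),
    node_type = c(rep("herb", nrow(graph$herbs)),
                  rep("target", nrow(graph$targets)),
                  rep("auxiliary", nrow(graph$auxiliary))),
    label = c(graph$herbs$name, graph$targets$name, graph$auxiliary$name),
    attributes = c(vapply(graph$attributes, paste, character(1), collapse = ";"),
                   rep("", nrow(graph$targets) + nrow(graph$auxiliary))),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    from = c(graph$relations$herb_id, graph$aux_edges$source),
    to = c(graph$relations$target_id, graph$aux_edges$target),
    ontology_term = c(graph$relations$ontology_term,
                      graph$aux_edges$ontology_term),
    provenance = c(graph$relations$provenance, graph$aux_edges$provenance),
    stringsAsFactors = FALSE)
  if (materialize_vocab) {
    vocab_nodes <- data.frame(
      name = c(paste0("attr:", graph$attribute_vocabulary),
               paste0("ont:", graph$ontology_vocabulary)),
      node_type = c(rep("attribute", length(graph$attribute_vocabulary)),
                    rep("ontology_term", length(graph$ontology_vocabulary))),
      label = c(graph$attribute_vocabulary, graph$ontology_vocabulary),
      attributes = "", stringsAsFactors = FALSE)
    nodes <- rbind(nodes, vocab_nodes)
    has <- lapply(graph$attributes, function(v) paste0("attr:", v))
    attr_edges <- data.frame(
      from = rep(names(has), lengths(has)),
      to = unlist(has, use.names = FALSE),
      ontology_term = "has_attribute", provenance = "",
      stringsAsFactors = FALSE)
    if (nrow(attr_edges)) edges <- rbind(edges, attr_edges)
  }
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' Import a node-link JSON graph written by [kg_export()]
#'
#' @param path path to the JSON file.
#' @return A `herb_kg` isomorphic to the exported graph.
#' @export
kg_import_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(doc$nodes, stringsAsFactors = FALSE)
  links <- as.data.frame(doc$links, stringsAsFactors = FALSE)
  if (!nrow(links))
    links <- data.frame(source = character(), target = character(),
                        ontology_term = character(), provenance = character(),
                        stringsAsFactors = FALSE)
  herbs <- nodes[nodes$node_type == "herb", , drop = FALSE]
  targets <- nodes[nodes$node_type == "target", c("id", "name"), drop = FALSE]
  auxiliary <- nodes[nodes$node_type == "auxiliary", c("id", "name"), drop = FALSE]
  is_rel <- links$source %in% herbs$id & links$target %in% targets$id
  relations <- links[is_rel, , drop = FALSE]
  names(relations)[1:2] <- c("herb_id", "target_id")
  knowledge_graph(herbs = herbs, targets = targets, relations = relations,
                  auxiliary = auxiliary,
                  aux_edges = links[!is_rel, , drop = FALSE],
                  attribute_vocabulary = unlist(doc$attribute_vocabulary),
                  ontology_vocabulary = unlist(doc$ontology_vocabulary))
}

#' Write a knowledge graph back to node/edge TSV tables
#'
#' Inverse of [kg_load()]; declared-but-unobserved vocabulary labels are
#' emitted as `#!` header declarations so the round trip is lossless.
#'
#' @param graph a `herb_kg`.
#' @param node_table,edge_table output paths.
#' @return Named list of the two paths, invisibly.
#' @export
kg_write_tables <- function(graph, node_table, edge_table) {
  stopifnot(inherits(graph, "herb_kg"))
  nodes <- data.frame(
    id = c(graph$herbs$id, graph$targets$id, graph$auxiliary$id),
    node_type = c(rep("herb", nrow(graph$herbs)),
                  rep("target", nrow(graph$targets)),
                  rep("auxiliary", nrow(graph$auxiliary))),
    name = c(graph$herbs$name, graph$targets$name, graph$auxiliary$name),
    attributes = c(vapply(graph$attributes, paste, character(1), collapse = ";"),
                   rep("", nrow(graph$targets) + nrow(graph$auxiliary))),
    stringsAsFactors = FALSE)
  observed_attr <- unique(unlist(graph$attributes, use.names = FALSE))
  observed_ont <- unique(c(graph$relations$ontology_term,
                           graph$aux_edges$ontology_term))
  hdr <- c(
    paste("#! attribute", setdiff(graph$attribute_vocabulary, observed_attr)),
    paste("#! ontology", setdiff(graph$ontology_vocabulary, observed_ont)))
  hdr <- hdr[!hdr %in% c("#! attribute ", "#! ontology ")]
  con <- file(node_table, "w", encoding = "UTF-8")
  if (length(hdr)) writeLines(hdr, con)
  utils::write.table(nodes, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  edges <- rbind(
    stats::setNames(graph$relations,
                    c("source", "target", "ontology_term", "provenance")),
    graph$aux_edges)
  utils::write.table(edges, edge_table, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(list(node_table = node_table, edge_table = edge_table))
}
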