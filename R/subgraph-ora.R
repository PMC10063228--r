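# Combination subgraph extraction and hypergeometric pathway
# over-representation analysis (ORA) on the combination's joint target set.

#' Extract the induced subgraph of a drug combination
#'
#' The subgraph keeps the member herbs, the union of their targets, and every
#' herb-to-target relation among them; it is itself a `herb_kg`, so it can be
#' exported with [kg_export()] for network-visualization tools. The pooled
#' medicinal-attribute summary counts, per label, how many members carry it.
#'
#' @param graph a `herb_kg`.
#' @param combination character vector of herb ids (size >= 2).
#' @return An object of class `kg_subgraph` (also `herb_kg`) with extra
#'   fields `combination`, `target_ids`, `attribute_summary`.
#' @export
extract_subgraph <- function(graph, combination) {
  stopifnot(inherits(graph, "herb_kg"))
  combination <- .validate_combination(graph, combination)
  target_ids <- sort(unique(unlist(lapply(combination, kg_targets_of,
                                          graph = graph))))
  herbs <- graph$herbs[graph$herbs$id %in% combination, , drop = FALSE]
  herbs$attributes <- I(unname(graph$attributes[herbs$id]))
  targets <- graph$targets[graph$targets$id %in% target_ids, , drop = FALSE]
  relations <- graph$relations[
    graph$relations$herb_id %in% combination &
      graph$relations$target_id %in% target_ids, , drop = FALSE]
  sub <- knowledge_graph(herbs = herbs, targets = targets,
                         relations = relations)
  labs <- unlist(graph$attributes[combination], use.names = FALSE)
  sub$combination <- combination
  sub$target_ids <- target_ids
  sub$attribute_summary <- if (length(labs)) {
    tab <- table(labs)
    data.frame(attribute = names(tab), members = as.integer(tab),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(attribute = character(), members = integer(),
               stringsAsFactors = FALSE)
  }
  class(sub) <- c("kg_subgraph", class(sub))
  sub
}

#' Read pathway sets from a GMT file
#'
#' Standard GMT dialect: one pathway per line, `name TAB description TAB
#' member TAB member ...`. Lines without at least one member are rejected.
#'
#' @param path path to the GMT file.
#' @return Named list of pathway sets, each a list with `name`,
#'   `description`, `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(fields) < 3 || !length(members))
      stop("GMT line ", i, ": expected name, description and >= 1 member")
    out[[i]] <- list(name = fields[1], description = fields[2],
                     members = unique(members))
  }
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write pathway sets to a GMT file
#'
#' @param pathways named list as returned by [read_gmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p)
    paste(c(p$name, p$description, p$members), collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, tests whether the hit set is enriched in the pathway
#' relative to the universe (the graph's target set, in typical use) with the
#' one-sided hypergeometric upper tail
#' `p = P(X >= k | N, K, n)`. Benjamini-Hochberg q-values are computed across
#' the tested pathways; the significance flag follows the raw `p < alpha`
#' criterion, with q reported alongside for a stricter reading. Pathway
#' members outside the universe are intersected away (a message reports the
#' drop); pathways empty after intersection are skipped.
#'
#' @param hit_targets character vector of hit target ids (must lie in
#'   `universe`).
#' @param pathways named list of pathway sets as from [read_gmt()].
#' @param universe character vector, the sampling frame of the test.
#' @param alpha raw-p significance threshold.
#' @return data.frame sorted by ascending p with columns `pathway`, `N`, `K`,
#'   `n`, `k`, `p_value`, `q_value`, `significant`.
#' @export
ora_test <- function(hit_targets, pathways, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty")
  hit_targets <- unique(as.character(hit_targets))
  outside <- setdiff(hit_targets, universe)
  if (length(outside))
    stop("hit target(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  N <- length(universe)
  n <- length(hit_targets)
  rows <- lapply(pathways, function(p) {
    members <- intersect(p$members, universe)
    dropped <- length(p$members) - length(members)
    if (dropped > 0)
      message("pathway '", p$name, "': ", dropped,
              " member(s) outside the universe dropped")
    if (!length(members)) return(NULL)
    K <- length(members)
    k <- length(intersect(hit_targets, members))
    # upper tail P(X >= k); phyper(k-1, ..., lower.tail = FALSE)
    p_val <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = p$name, N = N, K = K, n = n, k = k,
               p_value = p_val, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(pathway = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$pathway, method = "radix"), , drop = FALSE]
  res$significant <- res$p_value < alpha
  rownames(res) <- NULL
  res
}

#' Run ORA for a drug combination against the graph's target universe
#'
#' Convenience wrapper: the hit set is the combination's joint target set and
#' the universe is the full target set of the graph.
#'
#' @param graph a `herb_kg`.
#' @param combination character vector of herb ids.
#' @param pathways named list of pathway sets.
#' @param alpha raw-p significance threshold.
#' @return As [ora_test()].
#' @export
combination_ora <- function(graph, combination, pathways, alpha = 0.05) {
  sub <- extract_subgraph(graph, combination)
  ora_test(sub$target_ids, pathways, universe = graph$targets$id,
           alpha = alpha)
}
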