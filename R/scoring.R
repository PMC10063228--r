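# Combination scoring: total = f * g * sum_i ||(h1, h2, h3)||
#   f  - contraindication penalty, 0/1
#   g  - target diversity, 1 - w/t with w = targets hit by >= 2 members
#   h1 - per-herb target-hitting rate n_i / t
#   h2 - phenotype relativeness c2 / x
#   h3 - literature relativeness log10(l * (j + k) + 1)
# The per-herb triple is aggregated with a vector norm (L2 by default).

#' Read contraindication rules from a TSV file
#'
#' Columns: `kind` (one of herb_pair, attribute_pair, herb_attribute),
#' `left`, `right`, `note`.
#'
#' @param path path to the rules TSV.
#' @return data.frame of rules (possibly empty).
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  r <- .read_tsv(path)
  if (!nrow(r))
    return(data.frame(kind = character(), left = character(),
                      right = character(), note = character(),
                      stringsAsFactors = FALSE))
  if (!all(c("kind", "left", "right") %in% names(r)))
    stop("rules table must have columns kind, left, right")
  if (!"note" %in% names(r)) r$note <- ""
  bad <- which(!r$kind %in% c("herb_pair", "attribute_pair", "herb_attribute"))
  if (length(bad))
    stop("rule row ", bad[1], " has unknown kind '", r$kind[bad[1]], "'")
  bad <- which(r$kind == "herb_pair" & r$left == r$right)
  if (length(bad))
    stop("rule row ", bad[1], " is a herb_pair with identical sides")
  r[c("kind", "left", "right", "note")]
}

#' Read per-herb phenotype/literature evidence from a TSV file
#'
#' Columns: `herb_id`, `c2` (phenotype co-occurrence flag, 0/1), `l`
#' (publication count), `j` (cell-line validation flag), `k` (tissue
#' validation flag).
#'
#' @param path path to the evidence TSV.
#' @return data.frame of evidence records.
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  e <- .read_tsv(path)
  if (!all(c("herb_id", "c2", "l", "j", "k") %in% names(e)))
    stop("evidence table must have columns herb_id, c2, l, j, k")
  for (cn in c("c2", "l", "j", "k")) e[[cn]] <- as.numeric(e[[cn]])
  validate_evidence(e)
  e
}

validate_evidence <- function(evidence) {
  stopifnot(is.data.frame(evidence))
  if (!nrow(evidence)) return(invisible(evidence))
  if (anyDuplicated(evidence$herb_id))
    stop("duplicate evidence record for herb '",
         evidence$herb_id[duplicated(evidence$herb_id)][1], "'")
  if (!all(evidence$c2 %in% c(0, 1)) || !all(evidence$j %in% c(0, 1)) ||
      !all(evidence$k %in% c(0, 1)))
    stop("evidence flags c2, j, k must be 0 or 1")
  if (any(evidence$l < 0)) stop("publication counts l must be non-negative")
  invisible(evidence)
}

.validate_combination <- function(graph, combination) {
  combination <- trimws(as.character(combination))
  if (anyDuplicated(combination))
    stop("combination contains duplicate members")
  if (length(combination) < 2)
    stop("a combination needs at least 2 herbs")
  missing <- setdiff(combination, graph$herbs$id)
  if (length(missing))
    stop("combination member(s) not in graph: ", paste(missing, collapse = ", "))
  sort(combination)
}

#' Contraindication penalty for a combination
#'
#' Returns `f = 0` (with the violated rules) when the combination falls under
#' any contraindication rule, and `f = 1` otherwise. A `herb_pair` rule
#' matches when both herbs are members; an `attribute_pair` rule when the
#' pooled medicinal-attribute set of the members contains both labels; a
#' `herb_attribute` rule when the herb is a member and the attribute occurs on
#' a different member.
#'
#' @param graph a `herb_kg`.
#' @param combination character vector of herb ids (size >= 2).
#' @param rules data.frame of rules as from [read_rules()].
#' @return List with elements `f` (0 or 1) and `violated` (data.frame of
#'   matching rules).
#' @export
contraindication_penalty <- function(graph, combination, rules) {
  stopifnot(inherits(graph, "herb_kg"))
  combination <- .validate_combination(graph, combination)
  rules <- .validate_rules(graph, rules)
  if (!nrow(rules))
    return(list(f = 1, violated = rules))
  pooled <- lapply(combination, function(h) graph$attributes[[h]])
  names(pooled) <- combination
  pooled_all <- unique(unlist(pooled, use.names = FALSE))
  hit <- vapply(seq_len(nrow(rules)), function(i) {
    kind <- rules$kind[i]; L <- rules$left[i]; R <- rules$right[i]
    switch(kind,
      herb_pair = L %in% combination && R %in% combination,
      attribute_pair = L %in% pooled_all && R %in% pooled_all,
      herb_attribute = L %in% combination &&
        R %in% unique(unlist(pooled[setdiff(combination, L)],
                             use.names = FALSE)))
  }, logical(1))
  list(f = if (any(hit)) 0 else 1, violated = rules[hit, , drop = FALSE])
}

.validate_rules <- function(graph, rules) {
  if (is.null(rules) || !nrow(rules)) {
    return(data.frame(kind = character(), left = character(),
                      right = character(), note = character(),
                      stringsAsFactors = FALSE))
  }
  if (!"note" %in% names(rules)) rules$note <- ""
  herb_side <- function(kind) kind %in% c("herb_pair", "herb_attribute")
  for (i in seq_len(nrow(rules))) {
    kind <- rules$kind[i]
    if (!kind %in% c("herb_pair", "attribute_pair", "herb_attribute"))
      stop("rule row ", i, " has unknown kind '", kind, "'")
    lv <- if (herb_side(kind)) graph$herbs$id else graph$attribute_vocabulary
    if (!rules$left[i] %in% lv)
      stop("rule row ", i, ": left label '", rules$left[i],
           "' does not resolve against the graph")
    rv <- if (kind == "herb_pair") graph$herbs$id else graph$attribute_vocabulary
    if (!rules$right[i] %in% rv)
      stop("rule row ", i, ": right label '", rules$right[i],
           "' does not resolve against the graph")
  }
  rules[c("kind", "left", "right", "note")]
}

#' Target diversity of a combination
#'
#' `w` is the number of distinct targets hit by at least two distinct
#' members; `g = 1 - w/t` where `t` is the size of the graph's target
#' universe. Combinations whose members hit pairwise-disjoint target sets get
#' the maximal diversity `g = 1`.
#'
#' @inheritParams contraindication_penalty
#' @return List with elements `w` (overlap count) and `g` (in `[0, 1]`).
#' @export
target_diversity <- function(graph, combination) {
  stopifnot(inherits(graph, "herb_kg"))
  combination <- .validate_combination(graph, combination)
  t_total <- nrow(graph$targets)
  if (t_total == 0)
    stop("graph has no targets; diversity denominator undefined")
  counts <- tabulate(unlist(graph$adjacency[combination], use.names = FALSE),
                     nbins = t_total)
  w <- sum(counts >= 2L)
  list(w = w, g = 1 - w / t_total)
}

#' Per-herb score triples (h1, h2, h3) and their norms
#'
#' For each member: `h1 = n_i / t` (target-hitting rate), `h2 = c2 / x`
#' (phenotype relativeness), `h3 = c3 * log10(l * (j + k) + 1)` (literature
#' relativeness, `c3 = 1`), aggregated as the chosen vector norm. Members
#' without an evidence record are scored with all-zero evidence (warned).
#'
#' @inheritParams contraindication_penalty
#' @param evidence data.frame as from [read_evidence()], or `NULL`.
#' @param norm `"l2"` (Euclidean, default) or `"l1"`.
#' @return data.frame with columns `herb_id`, `h1`, `h2`, `h3`, `norm`.
#' @export
drug_score_triples <- function(graph, combination, evidence = NULL,
                               norm = c("l2", "l1")) {
  stopifnot(inherits(graph, "herb_kg"))
  norm <- match.arg(norm)
  combination <- .validate_combination(graph, combination)
  x <- length(combination)
  t_total <- nrow(graph$targets)
  if (t_total == 0)
    stop("graph has no targets; hitting-rate denominator undefined")
  ev <- .evidence_for(combination, evidence, warn = TRUE)
  h1 <- lengths(graph$adjacency[combination]) / t_total
  h2 <- ev$c2 / x
  h3 <- log10(ev$l * (ev$j + ev$k) + 1)
  nrm <- if (norm == "l2") sqrt(h1^2 + h2^2 + h3^2) else h1 + h2 + h3
  data.frame(herb_id = combination, h1 = h1, h2 = h2, h3 = h3, norm = nrm,
             row.names = NULL, stringsAsFactors = FALSE)
}

.evidence_for <- function(combination, evidence, warn = FALSE) {
  zero <- data.frame(herb_id = combination, c2 = 0, l = 0, j = 0, k = 0,
                     stringsAsFactors = FALSE)
  if (is.null(evidence) || !nrow(evidence)) {
    if (warn && !is.null(evidence))
      warning("no evidence records; scoring with all-zero evidence")
    return(zero)
  }
  validate_evidence(evidence)
  idx <- match(combination, evidence$herb_id)
  if (warn && anyNA(idx))
    warning("no evidence record for herb(s) ",
            paste(combination[is.na(idx)], collapse = ", "),
            "; treated as zero evidence")
  found <- !is.na(idx)
  zero[found, c("c2", "l", "j", "k")] <-
    evidence[idx[found], c("c2", "l", "j", "k")]
  zero
}

#' Score a drug combination
#'
#' Full decomposition of the combination score
#' `total = f * g * sum of per-herb norms`. The result is invariant under
#' member ordering (combinations are sets; the canonical form is the sorted
#' id vector).
#'
#' @inheritParams drug_score_triples
#' @param rules data.frame of contraindication rules, or `NULL`.
#' @return An object of class `kg_score`: list with `combination`, `f`, `w`,
#'   `g`, `triples`, `triple_sum`, `total`, `violated_rules`.
#' @examples
#' b <- simulate_kg(kg_sim_config(n_herbs = 10, n_targets = 8,
#'                                n_herb_target_edges = 20, n_auxiliary = 0,
#'                                n_auxiliary_edges = 0), seed = 1)
#' score_combination(b$graph, b$graph$herbs$id[1:3], b$rules, b$evidence)
#' @export
score_combination <- function(graph, combination, rules = NULL,
                              evidence = NULL, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  combination <- .validate_combination(graph, combination)
  pen <- contraindication_penalty(graph, combination, rules)
  div <- target_diversity(graph, combination)
  triples <- drug_score_triples(graph, combination, evidence, norm = norm)
  triple_sum <- sum(triples$norm)
  structure(list(
    combination = combination, f = pen$f, w = div$w, g = div$g,
    triples = triples, triple_sum = triple_sum,
    total = pen$f * div$g * triple_sum,
    violated_rules = pen$violated), class = "kg_score")
}

#' @export
print.kg_score <- function(x, ...) {
  cat("<kg_score> {", paste(x$combination, collapse = ", "), "}\n", sep = "")
  cat(sprintf("  f = %d  (violated rules: %d)\n", x$f, nrow(x$violated_rules)))
  cat(sprintf("  g = %.4f  (w = %d overlapping targets)\n", x$g, x$w))
  cat(sprintf("  sum of norms = %.4f\n", x$triple_sum))
  cat(sprintf("  total = %.4f\n", x$total))
  invisible(x)
}
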