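# Seeded random combination search: per round, draw `combos_per_round`
# uniform size-x herb subsets, score each, rank by total (ties broken by
# canonical form), keep the top k positive-scoring combinations; the
# cross-round consensus is the intersection of the per-round top-k sets.

#' Search configuration
#'
#' Defaults follow the published protocol: combinations of eight herbs, ten
#' rounds of one thousand random combinations each, top twenty kept per
#' round.
#'
#' @param x combination size (>= 2).
#' @param rounds number of independent rounds (>= 1).
#' @param combos_per_round random combinations drawn per round.
#' @param top_k per-round shortlist size.
#' @param seed base RNG seed; round `r` uses `seed + r`.
#' @param dedupe_within_round drop within-round duplicate combinations and
#'   resample to fill.
#' @param norm norm used in scoring ("l2" or "l1").
#' @return A `kg_search_config` list.
#' @export
search_config <- function(x = 8, rounds = 10, combos_per_round = 1000,
                          top_k = 20, seed = 1, dedupe_within_round = TRUE,
                          norm = "l2") {
  stopifnot(x >= 2, rounds >= 1, combos_per_round >= top_k, top_k >= 1)
  structure(list(x = as.integer(x), rounds = as.integer(rounds),
                 combos_per_round = as.integer(combos_per_round),
                 top_k = as.integer(top_k), seed = as.integer(seed),
                 dedupe_within_round = isTRUE(dedupe_within_round),
                 norm = match.arg(norm, c("l2", "l1"))),
            class = "kg_search_config")
}

.canonical_key <- function(ids) paste(sort(ids), collapse = "|")

#' Sample random drug combinations
#'
#' Draws `count` combinations of `x` distinct herbs, each sampled uniformly
#' without replacement from the graph's herb set; fully reproducible from
#' `seed`.
#'
#' @param graph a `herb_kg`.
#' @param x combination size.
#' @param count number of combinations.
#' @param seed RNG seed.
#' @param dedupe drop duplicate combinations (by canonical form) and resample
#'   to fill.
#' @return List of sorted herb-id character vectors.
#' @export
sample_combinations <- function(graph, x, count, seed, dedupe = TRUE) {
  stopifnot(inherits(graph, "herb_kg"))
  n <- nrow(graph$herbs)
  if (x > n) stop("cannot draw ", x, " distinct herbs from ", n)
  ids <- graph$herbs$id
  set.seed(seed)
  out <- vector("list", count)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  i <- 0L
  attempts <- 0L
  max_attempts <- 100L * count + 1000L
  while (i < count) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not draw ", count, " distinct combinations of size ", x,
           " from ", n, " herbs")
    combo <- sort(ids[sample.int(n, x)])
    key <- paste(combo, collapse = "|")
    if (dedupe) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
    }
    i <- i + 1L
    out[[i]] <- combo
  }
  out
}

# Precomputed scorer: per-herb norms depend only on the herb and x, so for a
# fixed combination size each herb's norm is computed once; only the penalty
# f and the overlap w depend on the member set. Equivalence with
# score_combination is asserted in the test suite.
.search_engine <- function(graph, rules, evidence, x, norm = "l2") {
  t_total <- nrow(graph$targets)
  if (t_total == 0) stop("graph has no targets")
  rules <- .validate_rules(graph, rules)
  ids <- graph$herbs$id
  ev <- .evidence_for(ids, evidence, warn = FALSE)
  if (!is.null(evidence) && nrow(evidence)) {
    unmatched <- setdiff(ids, evidence$herb_id)
    if (length(unmatched))
      message(length(unmatched), " herb(s) without evidence records; ",
              "treated as zero evidence")
  }
  h1 <- lengths(graph$adjacency[ids]) / t_total
  h2 <- ev$c2 / x
  h3 <- log10(ev$l * (ev$j + ev$k) + 1)
  herb_norm <- if (norm == "l2") sqrt(h1^2 + h2^2 + h3^2) else h1 + h2 + h3
  names(herb_norm) <- ids
  adj <- graph$adjacency
  attrs <- graph$attributes

  herb_pairs <- rules[rules$kind == "herb_pair", , drop = FALSE]
  attr_pairs <- rules[rules$kind == "attribute_pair", , drop = FALSE]
  herb_attr <- rules[rules$kind == "herb_attribute", , drop = FALSE]

  score_one <- function(combo) {
    f <- 1
    if (nrow(herb_pairs) &&
        any(herb_pairs$left %in% combo & herb_pairs$right %in% combo))
      f <- 0
    if (f == 1 && (nrow(attr_pairs) || nrow(herb_attr))) {
      member_attrs <- attrs[combo]
      pooled <- unique(unlist(member_attrs, use.names = FALSE))
      if (nrow(attr_pairs) &&
          any(attr_pairs$left %in% pooled & attr_pairs$right %in% pooled))
        f <- 0
      if (f == 1 && nrow(herb_attr)) {
        for (i in seq_len(nrow(herb_attr))) {
          h <- herb_attr$left[i]
          if (h %in% combo &&
              herb_attr$right[i] %in%
                unique(unlist(member_attrs[setdiff(combo, h)],
                              use.names = FALSE))) {
            f <- 0
            break
          }
        }
      }
    }
    counts <- tabulate(unlist(adj[combo], use.names = FALSE), nbins = t_total)
    w <- sum(counts >= 2L)
    g <- 1 - w / t_total
    ts <- sum(herb_norm[combo])
    c(f = f, w = w, g = g, triple_sum = ts, total = f * g * ts)
  }
  list(score_one = score_one, t_total = t_total)
}

.rank_combos <- function(combos, mat) {
  keys <- vapply(combos, paste, character(1), collapse = "|")
  ord <- order(-mat[, "total"], keys, method = "radix")
  df <- as.data.frame(mat[ord, , drop = FALSE])
  df$key <- keys[ord]
  df$rank <- seq_len(nrow(df))
  list(df = df[c("rank", "key", "f", "w", "g", "triple_sum", "total")],
       combos = combos[ord])
}

#' Run the multi-round random combination search
#'
#' Each round draws its combinations with seed `config$seed + round_index`,
#' scores them, ranks descending by total score with ties broken by
#' lexicographic canonical form, and records the top-k positive-scoring
#' combinations plus distribution summaries (mean, sd, skewness, excess
#' kurtosis). Zero-score (rule-violating or evidence-free) combinations never
#' enter a top-k list. The consensus is the set of combinations present in
#' every round's top-k.
#'
#' @param graph a `herb_kg`.
#' @param rules contraindication rules data.frame, or `NULL`.
#' @param evidence evidence data.frame, or `NULL`.
#' @param config a [search_config()].
#' @return An object of class `kg_search`: list with `config`, `rounds` (each
#'   holding `round_index`, `scored`, `combos`, `top_k`, `summary`) and
#'   `consensus` (list of combinations).
#' @export
run_search <- function(graph, rules = NULL, evidence = NULL,
                       config = search_config()) {
  stopifnot(inherits(graph, "herb_kg"), inherits(config, "kg_search_config"))
  engine <- .search_engine(graph, rules, evidence, config$x, config$norm)
  rounds <- vector("list", config$rounds)
  for (r in seq_len(config$rounds)) {
    combos <- sample_combinations(graph, config$x, config$combos_per_round,
                                  seed = config$seed + r,
                                  dedupe = config$dedupe_within_round)
    mat <- t(vapply(combos, engine$score_one, numeric(5)))
    ranked <- .rank_combos(combos, mat)
    pos <- ranked$df$total > 0
    keep <- which(pos)[seq_len(min(config$top_k, sum(pos)))]
    totals <- ranked$df$total
    rounds[[r]] <- list(
      round_index = r,
      scored = ranked$df,
      combos = ranked$combos,
      top_k = ranked$combos[keep],
      top_k_keys = ranked$df$key[keep],
      summary = score_summary(totals))
  }
  consensus_keys <- Reduce(intersect, lapply(rounds, `[[`, "top_k_keys"))
  consensus_keys <- sort(consensus_keys)
  structure(list(
    config = config, rounds = rounds,
    consensus = lapply(strsplit(consensus_keys, "|", fixed = TRUE), identity),
    consensus_keys = consensus_keys), class = "kg_search")
}

#' Distribution summary of a vector of scores
#'
#' @param totals numeric vector.
#' @return Named list: mean, sd, skewness, excess kurtosis, min, max.
#' @export
score_summary <- function(totals) {
  m <- mean(totals)
  s <- stats::sd(totals)
  d <- totals - m
  m2 <- mean(d^2)
  list(mean = m, sd = s,
       skewness = if (m2 > 0) mean(d^3) / m2^1.5 else NA_real_,
       excess_kurtosis = if (m2 > 0) mean(d^4) / m2^2 - 3 else NA_real_,
       min = min(totals), max = max(totals))
}

#' Cross-round consensus of top-k lists
#'
#' @param rounds list of round results as produced by [run_search()].
#' @return List of combinations (sorted id vectors) present in every round's
#'   top-k, in lexicographic order of canonical form.
#' @export
consensus_topk <- function(rounds) {
  stopifnot(length(rounds) >= 1)
  keys <- Reduce(intersect, lapply(rounds, `[[`, "top_k_keys"))
  lapply(strsplit(sort(keys), "|", fixed = TRUE), identity)
}

#' Pooled ranking across all rounds
#'
#' Merges every scored combination from every round, deduplicates by
#' canonical form, and re-ranks by total (ties by canonical form).
#'
#' @param search a `kg_search` result.
#' @return data.frame with `rank`, `key`, `total` and score components.
#' @export
pooled_ranking <- function(search) {
  stopifnot(inherits(search, "kg_search"))
  all_df <- do.call(rbind, lapply(search$rounds, `[[`, "scored"))
  all_df <- all_df[!duplicated(all_df$key), , drop = FALSE]
  ord <- order(-all_df$total, all_df$key, method = "radix")
  all_df <- all_df[ord, , drop = FALSE]
  all_df$rank <- seq_len(nrow(all_df))
  rownames(all_df) <- NULL
  all_df
}

#' Exhaustively score and rank every size-x combination
#'
#' Complete enumeration oracle for small graphs, using the same scoring and
#' ranking rule as [run_search()].
#'
#' @inheritParams run_search
#' @param x combination size.
#' @param cap refuse enumerations larger than this many combinations.
#' @param norm scoring norm.
#' @return List with `ranking` (data.frame) and `combos` (list, ranking
#'   order).
#' @export
exhaustive_ranking <- function(graph, rules = NULL, evidence = NULL, x,
                               cap = 1e5, norm = "l2") {
  stopifnot(inherits(graph, "herb_kg"))
  n <- nrow(graph$herbs)
  n_combos <- choose(n, x)
  if (n_combos > cap)
    stop("refusing to enumerate ", format(n_combos, big.mark = ","),
         " combinations (cap ", format(cap, big.mark = ","), ")")
  engine <- .search_engine(graph, rules, evidence, x, norm)
  idx <- utils::combn(n, x, simplify = FALSE)
  combos <- lapply(idx, function(i) sort(graph$herbs$id[i]))
  mat <- t(vapply(combos, engine$score_one, numeric(5)))
  ranked <- .rank_combos(combos, mat)
  list(ranking = ranked$df, combos = ranked$combos)
}

#' @export
print.kg_search <- function(x, ...) {
  cat("<kg_search> ", x$config$rounds, " round(s) x ",
      x$config$combos_per_round, " combinations of size ", x$config$x,
      "; top ", x$config$top_k, " per round\n", sep = "")
  cat("  consensus combinations: ", length(x$consensus), "\n", sep = "")
  invisible(x)
}
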