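---
title: "Scoring and searching herbal drug combinations on a knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and searching herbal drug combinations on a knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbkg)
```

## The problem

Multi-herb formulas in traditional Chinese medicine are designed to act
synergistically: several drug entities hitting many *discrete* cellular
targets of an immuno-inflammatory disease, while respecting
Pharmacopoeia-style incompatibility (contraindication) rules. `herbkg`
operationalizes this as optimization over a typed herb–target knowledge
graph: herbs carry medicinal-attribute labels (a 64-label vocabulary at the
reference scale), herb→target edges carry one of 13 relation-ontology
terms, and the target universe (240 targets at reference scale) defines the
denominators of the scoring function.

## The scoring model

For a combination \(C\) of \(x \ge 2\) herbs,

\[\mathrm{Score}(C) = f(C)\; g(C) \sum_{i=1}^{x}
  \left\lVert (h_{1,i},\, h_{2,i},\, h_{3,i}) \right\rVert .\]

**Penalty \(f \in \{0,1\}\).** Any matching contraindication rule zeroes
the score. Three rule kinds are supported: `herb_pair` (both herbs are
members), `attribute_pair` (the pooled attribute set of the members
contains both labels), and `herb_attribute` (the herb is a member and the
attribute occurs on a *different* member — a herb is never contraindicated
against its own attributes).

**Diversity \(g = 1 - w/t \in [0,1]\).** \(w\) counts distinct targets hit
by at least two distinct members and \(t\) is the size of the target
universe. Members with pairwise-disjoint target sets give \(g = 1\).
Multiple relations between the same herb and target (different ontology
terms) collapse to one logical link everywhere in scoring: the definitions
count targets, not edges.

**Per-herb triple.** \(h_1 = n_i/t\) is the target-hitting rate;
\(h_2 = c_2/x\) the phenotype relativeness (\(c_2 \in \{0,1\}\): literature
co-occurrence with the disease phenotype); and
\(h_3 = c_3 \log_{10}(l\,(j+k) + 1)\) the literature relativeness, with
\(l\) the publication count, \(j,k \in \{0,1\}\) cell-line and tissue
validation flags, and \(c_3 = 1\).

Numerical choices made where the formulas leave room:

* **Norm.** \(\lVert\cdot\rVert\) is read as a per-herb vector norm inside
  a sum over members; the Euclidean (L2) norm is the default reading and an
  L1 option is exposed (`norm = "l1"`).
* **Logarithm.** The base of the log in \(h_3\) is taken as 10 with a
  \(+1\) additive guard, so zero evidence (\(l = 0\) or \(j = k = 0\))
  gives \(h_3 = 0\) rather than \(-\infty\), and more evidence always means
  larger \(h_3\).
* **Per-entity evidence.** \(h_3\) is computed from each member's own
  \((l, j, k)\); the evidence terms are not pooled across the combination,
  since the triple is defined per drug entity.
* **Missing evidence.** A member without an evidence record scores
  \(c_2 = l = j = k = 0\) with a warning, not an error, so large graphs
  need not annotate every herb.
* **Degenerate inputs.** A graph with zero targets makes the \(1/t\)
  denominators undefined and is rejected; combinations must have \(x \ge
  2\) distinct members that all resolve in the graph.

One property worth stating precisely: adding a member whose target set is
disjoint from the others never changes \(w\), but it *can* lower the norm
sum when members carry phenotype evidence, because \(h_2 = c_2/x\) shrinks
for every member as \(x\) grows. The monotonicity of the norm sum therefore
holds unconditionally only for phenotype-free evidence, and the test suite
checks it in that regime.

## The search protocol

The reference protocol draws, per round, 1000 combinations of 8 herbs
uniformly without replacement from the herb set, scores them, and ranks
descending by total score with ties broken by the lexicographic order of
the canonical form (the sorted id vector), giving a deterministic total
order. The top 20 positive-scoring combinations per round are kept
(zero-score, i.e. rule-violating, combinations never enter a shortlist),
and the cross-round consensus is the intersection of the per-round top-k
sets. Round \(r\) uses seed `seed + r`, so partial reruns are reproducible,
and identical inputs give bit-identical results. Within a round, duplicate
draws are removed and resampled by default; across rounds, draws are
independent. A pooled ranking over all rounds is exposed alongside
(`pooled_ranking()`), and `exhaustive_ranking()` enumerates the full
\(\binom{n}{x}\) space (capped, default \(10^5\)) with the same ranking
rule as the verification oracle.

A structural caveat the package states plainly: under uniform sampling the
probability that one *specific* size-8 combination out of
\(\binom{345}{8} \approx 4\times10^{15}\) is independently drawn in every
one of 10 rounds of 1000 draws is astronomically small
(\(\sim 10^{-126}\)). A consensus set that is non-empty at that scale
therefore cannot arise from uniform independent rounds; it requires either
a much smaller effective candidate space or a non-uniform (e.g.
relevance-biased) generator. The consensus machinery is exact and useful on
small spaces — where rounds genuinely re-draw combinations — and the
planted-combination validation below uses the attainable guarantees
(percentile dominance, argmax containment) at full scale. Normality of the
per-round score distributions is summarized (mean, sd, skewness, excess
kurtosis) but never asserted: it is a descriptive observation, not a model
assumption.

## Subgraph extraction and pathway over-representation

`extract_subgraph()` induces the herb + joint-target subgraph of a
combination (exportable to GraphML for Cytoscape-style viewing) and pools
the members' medicinal attributes with per-label member counts.
`ora_test()` performs the standard one-sided hypergeometric
over-representation test per pathway set, \(p = P(X \ge k \mid N, K, n)\),
with the graph's target set as the universe \(N\) — the graph defines the
sampling frame of the method, so an all-gene universe would be wrong here.
Benjamini–Hochberg q-values are reported alongside, but the significance
flag follows the raw \(p < \alpha\) criterion (default 0.05), matching how
such enrichment maps are usually thresholded; users wanting multiplicity
control can filter on `q_value`. Only over-representation is tested;
depletion is out of scope. Pathway members outside the universe are
intersected away with a message; GMT lines without members are rejected at
parse time.

## The synthetic generator

The generator emulates the *scale and schema* of the reference graph, not
its content: 345 herbs, 240 targets, 64 attribute labels, 13 ontology
terms, and 233 auxiliary phenotype/disease/evidence nodes, for 895 nodes
under the materialized bookkeeping convention in which vocabulary labels
count as nodes (the published total is only decomposable that way;
`kg_stats(..., materialize_vocab = FALSE)` gives the labels-only count).
The 2197-edge budget is split as 1600 herb→target relations (mean herb
degree ≈ 4.6, a plausible curation density) plus 597 auxiliary edges, with
every auxiliary node connected; the true split is not published, so this is
a configuration default, exposed in `kg_sim_config()`.

Herb degrees follow a gamma-weight multinomial: weights with mean 1 and
variance equal to the `concentration` parameter (default 0.5) feed a
multinomial over the edge budget, so `concentration → 0` recovers uniform
edge assignment (the per-herb degree variance converges to the binomial
\(E\,p(1-p)\), which the test suite checks by Monte Carlo) and larger
values give heavy-tailed degrees. Evidence is drawn per herb: Bernoulli
phenotype flag (default 0.3), geometric publication counts (default mean
3 — a heavy right tail, matching citation-count folklore), Bernoulli
validation flags (0.4 cell line, 0.3 tissue). Contraindication rules are
random herb pairs (8) and attribute pairs (4).

`plant_combination()` rewires a chosen set of `x` herbs so their joint
target set has exactly the requested size (default 46 for 8 herbs) with
zero pairwise overlap, boosts their evidence (\(c_2 = 1\), \(l = 500\),
\(j = k = 1\)), drops rules naming them and reassigns their attributes to
rule-free labels. The planted combination is thus guaranteed viable and, by
construction, scores far above random same-size combinations.

What passing tests on synthetic data do **not** show: the generator knows
nothing about real herb–target biology, real degree distributions, real
rule structure, or correlations between evidence and connectivity. Green
tests demonstrate the algorithms' correctness and the pipeline's
determinism, not that the scoring function ranks real formulas well.

## Clinical comparison statistics

The clinical component reproduces two-arm trial statistics from *printed*
summary inputs (the shipped `inst/extdata/clinical.yaml` holds the
reference tables: 80 patients per arm):

* `chisq_2x2()` computes the uncorrected Pearson statistic
  \(\chi^2 = N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))\), df = 1. No
  Yates continuity correction is applied — the printed statistics are
  recovered exactly by the uncorrected formula and would not be by the
  corrected one. Tables with a zero margin are rejected.
* `t_from_summary()` computes the pooled-variance Student *t* with
  \(df = n_1+n_2-2\) from per-group \((n, \bar{y}, s)\); the Welch variant
  is exposed, and with equal group sizes the two statistics coincide, so
  the choice is cosmetic for the reference tables. Reproduction tolerance
  is bounded by the 2–3-decimal rounding of the printed means and SDs, not
  by the arithmetic.
* `rates_report()` renders `100·events/size` from exact rational
  arithmetic to two decimals.

Paired within-group *t* statistics are deliberately not computed: they
require within-patient correlations that summary tables do not carry. No
multiple-testing correction is applied across the clinical tests, matching
the presentation being reproduced.

## Problem sizes used in the test suite

The oracle-equivalence property runs 1000 random toy graphs (≤ 8 herbs,
≤ 12 targets) against a straight-from-the-definitions recomputation at
\(10^{-12}\); search-vs-exhaustive containment uses 12-herb graphs
(\(\binom{12}{3} = 220\) combinations, ≥ 50 % sampled per round) over 20
seeds; the planted-recovery protocol runs the full reference scale
(10 × 1000 size-8 draws, top 20, 20 seeded repetitions); ORA exactness
sweeps every \((N \le 25, K, n, k)\) instance against combinatorial
enumeration. These sizes make the whole suite complete in about a minute
while exercising each guarantee at the scale where its failure modes live.

## Known limitations

* The consensus-at-scale caveat above: uniform rounds cannot re-draw a
  specific size-8 combination from 345 herbs; consensus is meaningful on
  small candidate spaces or with a biased generator (not implemented —
  the reference protocol is pure uniform sampling + ranking).
* Chemical-ingredient–level scoring is out of scope; entities are whole
  herbs.
* No live pathway-database access: pathway sets are user-supplied GMT
  files, and no identifier mapping between target vocabularies is
  attempted.
* Expert curation of shortlists (the Jun-Chen-Zuo-Shi compositional roles)
  is a human step outside the algorithmic scope; the pipeline stops at the
  ranked consensus list.
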