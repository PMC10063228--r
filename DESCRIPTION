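Package: herbkg
Title: Knowledge-Graph Scoring and Search for Synergistic Herbal Drug Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and queries a typed herb-target knowledge graph for
    immunotherapy-oriented drug-combination design, scores candidate multi-herb
    combinations with a penalty/diversity/relativeness scoring function, runs a
    seeded multi-round random combination search with top-k cross-round
    consensus, extracts combination subgraphs with hypergeometric pathway
    over-representation analysis, and reproduces two-arm clinical comparison
    statistics (2x2 chi-square tests, two-sample t tests from group summaries,
    rate reports) from printed trial tables. A seeded synthetic-graph generator
    emulating the published graph's scale makes every component testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
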