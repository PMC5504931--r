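Package: chmnet
Title: Co-Prescription Network Analysis of Chinese Herbal Medicine Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mining multi-herb prescription patterns from
    claims-style ambulatory visit data. Implements a pharmacoepidemiologic
    inclusion/exclusion cascade over dispensed Chinese herbal medicine (CHM)
    records, level-wise (Apriori) frequent-itemset and association-rule
    mining with support/confidence/lift screens, construction of a
    co-prescription network from the top-ranked herb combinations with
    greedy-modularity community detection and core-herb identification, and
    prescription-level utilization summaries. A synthetic cohort generator
    with planted co-occurrence structure provides a recovery ground truth, so
    the whole pipeline is testable without access-restricted claims sources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
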