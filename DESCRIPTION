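Package: dfcstates
Title: Dynamic Functional Connectivity States, Temporal Metrics, and
    Clinical Impairment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved functional connectivity of
    resting-state component time-courses. Computes static and sliding-window
    Fisher-Z functional connectivity, clusters windowed connectivity into
    recurrent whole-brain states with city-block k-means (elbow and Dunn's
    index model selection), derives temporal state metrics (fraction time,
    mean dwell time, stickiness, transition counts), state-wise average
    connectivity and signed Louvain modularity, and across-state overall
    connectivity (ASOC) at the grand, intra-network, and inter-network
    level. Includes multi-domain clinical composite z-scores with an
    EDSS-based cohort split, a permutation/FDR statistical battery
    (permutation T-tests, family-structured Benjamini-Hochberg correction,
    age-residualised Kruskal-Wallis with Dunn's post-hoc tests, and
    age-controlled Spearman partial correlations), and a synthetic cohort
    generator producing state-switching component time-courses with known
    ground truth plus demographic and clinical tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
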