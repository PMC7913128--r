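Package: moscreen
Title: Multi-Objective Virtual Screening with Desirability Aggregation and
    Genetic-Algorithm Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-objective ligand-based virtual screening.
    Per-target activity probabilities from any probabilistic classifier are
    aggregated into a single desirability score per compound (mean predicted
    activity over selected targets times mean predicted inactivity over
    selected off-targets), and the subset of targets entering the aggregation
    is optimized with a genetic algorithm maximizing the BEDROC
    early-recognition metric. Includes the supporting bioactivity curation
    steps (activity labeling at 10 uM, replicate consensus at 75 percent
    agreement, target filters), class balancing by PCA + k-means +
    silhouette-guided proportional undersampling of circular fingerprints,
    early-recognition metrics (AUAC, enrichment factor, RIE, BEDROC and the
    alpha calibration solver), cluster-consensus target relevance and global
    desirability for drug repurposing, and a synthetic benchmark generator
    with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    yaml
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
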