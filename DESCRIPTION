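Package: ethorisk
Title: Risk-Assessment Ethometrics and Co-Expression Network Correlates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores risk-assessment behavior from rodent tracking
    trajectories in the elevated plus maze, dark/light box and open field
    (zone dwell indices, stretch-attend postures, protected head dips,
    hidden-entry-hidden transition frequency), compares groups with an
    adaptive test-selection procedure (Shapiro-Wilk and Levene routing to
    Student, Welch or Mann-Whitney tests), builds signed biweight
    midcorrelation co-expression networks with topological-overlap module
    detection and module eigengene trait correlation, and extracts hubs and
    dense subnetworks from confidence-scored protein-interaction edge lists.
    Includes synthetic-data generators with known ground truth for
    trajectories, expression matrices and interaction graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
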