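Package: hicpair
Title: Comparative Analysis of Paired Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing the three-dimensional genome architecture of
    two cell types from binned Hi-C contact maps. Implements iterative
    correction (symmetric matrix balancing), A/B compartment eigenvector
    tracks with regression-line comparison, per-bin difference detection by
    Euclidean distance, correlation and eigenvector distance with split-half
    bias filtering, per-contact differential testing under a uniform contact
    probability model with Bonferroni correction, contact-probability
    distance-scaling P(s) curves with power-law fits, cis/trans and
    interchromosomal interaction metrics, and a distance-wise "compression"
    normalization that rescales one map's P(s) onto another's while
    preserving within-distance contact ratios. Includes a synthetic contact
    map generator with known ground truth (power-law distance decay,
    plaid compartment structure, TAD-like blocks, planted differences) used
    throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
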