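Package: dnabubbles
Title: Torsional DNA Dynamics, Denaturation Bubbles, and Deuterium Substitution Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanical angular model of double-stranded DNA as two coupled
    chains of torsional pendulums with an energy-threshold hydrogen-bond
    break/restore rule, integrated with a fourth-order Runge-Kutta scheme.
    Provides a per-position single deuterium (2H/1H) substitution scanner
    over a grid of critical energies, run-length statistics of denaturation
    bubbles with size-group occupancy probabilities, an extremum-range
    ("BJ") classifier of substitution positions into Maximum/Minimum ranges
    with closed-state corrected counting and region-wise A-T/G-C
    bookkeeping, and the association statistics used to compare gene
    regions (Yates-corrected chi-squared, 3x2 chi-squared with Bonferroni
    adjustment, Kruskal-Wallis, Spearman rank correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
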