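Package: bbbccs
Title: Collision Cross Sections as a Descriptor of Blood-Brain Barrier Permeation
Version: 1.0.0
Authors@R:
    person("bbbccs", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate the ion-mobility collision cross section (CCS)
    as a molecular descriptor of blood-brain barrier (BBB) permeation of
    drugs. Implements charge-aware adduct selection for (M+H)+ / (M-H)-
    ions, the low-field Mason-Schamp conversion between drift-tube arrival
    times and CCS in nitrogen, hard-sphere conversion of CCS values into
    projected ion radii and areas (with a momentum-transfer correction) and
    their comparison against BBB pore dimensions, CCS-threshold and
    combined CCS/lipophilicity classification rules with confusion-matrix
    accuracy evaluation, a bagged classification-tree ensemble with
    out-of-bag permutation importance for descriptor ranking, and a
    synthetic compound-library generator with closed-form accuracy oracles
    so the whole pipeline is testable without external drug libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
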