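Package: splinetests
Title: Permutation Spline Tests for Longitudinal Grouped Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Hypothesis tests for longitudinal studies with irregular
    sampling, subject dropout, and non-normal variation, as are typical in
    microbiome time courses. Trajectories are summarized with local
    polynomial (loess) smoothers and tested by permutation: an overall
    two-group difference test based on the absolute area between group
    splines with a subject-label permutation null, a sliding interval-wise
    two-group test on per-subject splines with a data-density gate, and a
    single-group non-zero-trend test based on the signed area between the
    group spline and a flat baseline anchored at its start, with a
    within-subject time permutation null. Includes a seeded synthetic-data
    generator for perturbation, null, and trend scenarios, pre-configured
    plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
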