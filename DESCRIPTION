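Package: msnbiotypes
Title: Biotype Discovery from Topological Deviations in Morphometric
    Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for stratifying a clinical cohort by
    network-level deviations from normative brain development. Builds
    per-subject morphometric similarity networks from regional gray-matter
    value distributions (Kullback-Leibler divergence similarity), profiles
    hub topology (degree centrality, nodal efficiency, participation
    coefficient), fits warped Bayesian linear regression normative models of
    each nodal metric on age and sex, maps extreme deviations with group and
    spatial (spin) permutation inference, fuses metric-wise deviations by
    multiset CCA plus joint ICA, discovers case biotypes with a
    semi-supervised max-margin polytope (HYDRA) including nested
    cross-validated model selection and stability checks, transfers
    pretrained models to new cohorts via site recalibration and expression
    scores, and decodes deviation maps against spatial annotation maps with
    spin-test and PLS bootstrap inference. Includes a seeded multisite
    synthetic-cohort generator so the full chain is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    splines,
    tools,
    e1071,
    igraph,
    jsonlite,
    MASS,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
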