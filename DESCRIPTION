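Package: connectolesion
Title: Graph-Theoretical Analysis of Structural Connectomes After Focal Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and group-level analysis of weighted structural
    brain networks derived from tractography-style streamline counts.
    Builds volume-normalized connectivity matrices, applies proportional
    thresholding from a healthy-average reference, computes global graph
    parameters (median connectivity strength, global efficiency, Onnela
    clustering, modularity) with degree-, strength- and weight-preserving
    null-model normalization, and tests group differences with mixed-effects
    models, multi-threshold permutation correction over density sweeps,
    Bonferroni-corrected mass-univariate node tests and the network-based
    statistic. Includes a Watts-Strogatz lesion simulation that removes
    long-range connections, and a synthetic-cohort generator with planted
    ipsilesional deficits so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
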