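Package: plateletIFC
Title: Single-Event Platelet Aggregation Analysis for Imaging Flow Cytometry
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of single-event platelet aggregation
    measured by imaging flow cytometry of antibody-labelled whole blood.
    Provides a synthetic-data generator for per-event platelet images and
    full donor cohorts with known ground truth, conditional gating on
    CD42b-positive in-focus events, a small convolutional neural network
    that classifies each event as a singlet, doublet, triplet or multiplet,
    the weighted platelet aggregation (WPA) score, two-stage quality
    control (technical-replicate concordance and ROUT outlier removal on
    acquisition-date means), and the cohort-level statistical layer
    (condition contrasts, sex contrasts and age regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: FlowCytometry, SingleCell, Classification, QualityControl,
    StatisticalMethod
RoxygenNote: 7.3.3
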