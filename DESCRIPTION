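Package: chronet
Title: Chronotype Classification from Functional Brain Networks via the
    Network-Based Statistic
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds subject-level functional brain networks from ROI time
    series using Tikhonov-regularized partial correlation, finds
    group-contrast dysconnected networks with the network-based statistic
    (NBS) at the percolation threshold (minimum connected component), and
    classifies a held-out subject's chronotype (early vs late circadian
    phenotype) with a three-step four-network decision rule. Includes
    leave-one-out evaluation, t-statistic and significance threshold
    sweeps, leave-one-subject-out stability analysis, and a seeded
    synthetic cohort generator with planted subnetwork effects.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
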