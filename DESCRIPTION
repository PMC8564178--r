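Package: neurocouple
Title: Cerebral Blood Flow, Functional Connectivity Strength, and
    Neurovascular Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying neurovascular coupling across
    groups with different white-matter-hyperintensity loads. Quantifies
    cerebral blood flow from pseudo-continuous arterial spin labeling series
    with a single-compartment model, computes voxelwise functional
    connectivity strength from preprocessed resting-state BOLD, measures
    per-subject CBF-FCS coupling globally and per atlas region, and performs
    group inference (demographics tests, Freedman-Lane permutation ANCOVA
    with post-hoc contrasts, partial correlations) and percentile-bootstrap
    mediation analysis. Includes a synthetic-cohort generator so the whole
    pipeline is testable without scanner data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
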