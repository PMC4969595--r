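Package: revtraj
Title: Reversal and Trajectory Classification of Perturbation-Induced
    Expression Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies per-gene expression changes observed during
    transcription-factor-driven reprogramming of fibroblasts into
    reversal and favorability categories using fold-change thresholds.
    Reads TPM expression matrices and GMT gene sets, bins genes by
    perturbation fold change, labels treatment responses as reversed,
    consistent or unaffected, classifies gene trajectories as
    consistent, un-necessary, opposite or over-regulated relative to
    the somatic-to-pluripotent endpoint, summarizes direction fractions
    within pathways, and ships a seeded synthetic-data generator with
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
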