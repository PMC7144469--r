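Package: uqscreen
Title: Uncertainty-Aware Compound Activity Prediction and Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Curation of ChEMBL-style bioactivity records into per-compound
    log-Ki regression datasets, binary molecular fingerprints (Morgan radius-2
    and MACCS keys via an RDKit backend, plus synthetic fingerprints) with
    Tanimoto similarity, random k-fold and balanced-agglomerative-clustering
    (BAC) fold assignment, a dropout multi-layer-perceptron regressor with
    Monte-Carlo-dropout uncertainty estimation, uncertainty-augmented compound
    ranking strategies with precision-at-top evaluation, percentile-based
    detection of suspect activity records, and uncertainty diagnostics. A
    synthetic-data generator emulating clustered chemical space with repeated,
    occasionally corrupted measurements makes the whole pipeline testable
    end-to-end without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    ChemmineR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
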