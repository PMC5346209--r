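Package: most
Title: Most-Similar Ligand Target Inference with False Discovery Rate Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ligand-based target prediction from nearest-neighbour chemical
    similarity and explicit bioactivity. For a query compound the most-similar
    annotated ligand of each target is found by fingerprint Tanimoto similarity
    (Morgan/ECFP4 or FP2 via OpenBabel), and the pair (Tc_most, pKi_most) is fed
    into a trained probabilistic classifier (logistic regression, naive Bayes or
    random forest) to yield calibrated active/inactive probabilities. The
    inactive probability doubles as a per-target p-value, so multiple-target
    scans are corrected by Benjamini-Hochberg adjustment and Storey q-values.
    Includes Ki bioactivity curation from ChEMBL-style tables, sevenfold
    cross-validation, temporal validation, threshold trade-off analysis, and a
    synthetic-data generator for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    e1071,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
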