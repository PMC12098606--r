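Package: clinenrich
Title: Clinical Data Enrichment from Free-Text Pathology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage data-enrichment pipeline for oncology real-world
    evidence: extractive question answering locates biomarker value spans in
    free-text pathology reports, and a confidence-routed post-processing stage
    classifies each span into a closed, per-biomarker clinical vocabulary
    (FIGO stage, TNM, HER2, ER/PR, mismatch-repair status and others).
    Outputs are restricted to the closed vocabulary, so no patient-identifiable
    free text can leak. Includes a prototype cosine-similarity classifier and a
    contrastive few-shot classifier over deterministic character n-gram
    hashing embeddings, a labelled synthetic report generator for end-to-end
    testing without clinical data, and the full evaluation protocol
    (accuracy with Student-t confidence intervals across features, macro
    precision/recall/F1, Cohen's kappa, misclassification breakdowns and
    training-size learning curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
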