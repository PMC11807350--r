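Package: salmine
Title: Mining Self-Acknowledged Limitations in Randomized Controlled Trial Articles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects self-acknowledged limitation (SAL) sentences in the
    full text of randomized controlled trial articles and assigns them
    limitation types from a fixed two-level taxonomy (15 top-level and 24
    fine-grained categories). Provides section-aware sentence extraction,
    BRAT standoff annotation parsing and span-to-sentence label projection,
    inter-annotator agreement (Krippendorff's alpha with a MASI set
    distance, pairwise Cohen's kappa), a binary SAL sentence classifier and
    a multi-label type classifier with per-label dynamic thresholding, a
    rule-based Funding detector, class-balancing training-set augmentation
    (oversampling, EDA operators, RAKE keyword extraction, dual-view
    generation with consistency filtering), multi-label evaluation metrics
    with paired significance tests (McNemar, Bhapkar), corpus-level SAL
    profiling, and a deterministic synthetic-corpus generator so the whole
    pipeline can be exercised end-to-end offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
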