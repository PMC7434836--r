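Package: acpselect
Title: Low-Dimensional Feature Models for Anticancer Peptide Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building low-dimensional discriminative feature
    models of anticancer peptides (ACPs). Implements twelve peptide sequence
    descriptor families (amino acid, dipeptide, tripeptide and k-spaced pair
    compositions, their 5-group physicochemical analogues, conjoint triads,
    composition/transition/distribution descriptors, and pseudo and
    amphiphilic pseudo amino acid composition), a max-relevance-max-distance
    feature ranking with incremental cross-validated subset curves and
    slope-point ("knee") extraction, stratified cross-validation with pooled
    confusion-matrix metrics (Sn, Sp, Acc, MCC, F-score), an RBF-SVM grid
    search and a seeded random-forest harness, plus a synthetic labeled
    peptide generator with planted composition bias for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
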