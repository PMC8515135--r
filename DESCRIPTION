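Package: transcompr
Title: Cross-Species Translatable Components Regression for Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies disease signatures shared between human and mouse
    transcriptomes by projecting mouse expression profiles into a principal
    component space built from human data (Translatable Components
    Regression). Human components predictive of mouse disease status are
    selected by consensus LASSO over repeated stratified cross-validation,
    their significance is assessed against size-matched random-component and
    phenotype-permutation empirical nulls, disease information is decoupled
    from aging with a nested linear-model F-test, and selected components are
    interpreted through loading-tail over-representation analysis and
    gene-level tests. Includes a synthetic-data generator with planted
    cross-species structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
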