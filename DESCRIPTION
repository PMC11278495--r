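Package: classcontrast
Title: Class-Contrastive Explanations for Mortality Models on Clinical Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for explaining black-box mortality models fitted to binary
    clinical feature tables using class-contrastive reasoning. Trains logistic
    regression (plain and L1-regularised) and an autoencoder-plus-random-forest
    classifier behind a common predict-probability contract, perturbs sets of
    one to three binary features on held-out patients to quantify changes in
    predicted death probability, ablates matched training cases and refits to
    trace counter-intuitive model behaviour back to the data, flags
    zero-support feature combinations as potentially spurious, and renders
    clustered class-contrastive heatmaps, odds-ratio forest plots and templated
    textual explanations. Ships a synthetic-cohort simulator with a
    ground-truth manifest so the full pipeline is testable without access to
    private electronic health records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    glmnet,
    randomForest,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
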