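Package: epipair
Title: Image-Based Prediction of Paratope-Epitope Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether an antibody paratope and an antigen epitope bind
    by reducing each side of the interface to a feature-coloured 2D image and
    scoring the image pair with a small residual convolutional network.
    Includes PDB ingestion and dataset curation, PCA-based patch imaging,
    positive/negative sample construction with stratified splits, CNN training
    with cross-validation and mean-ensemble scoring, weight-activation
    attribution maps, docking-pose rescoring and rotation-sweep paratope
    library screening, plus synthetic toy-complex generators for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    bio3d,
    Biostrings,
    seqinr,
    pROC,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
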