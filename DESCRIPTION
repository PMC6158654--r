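Package: aodeep
Title: Antioxidant Protein Identification from g-Gap Dipeptide Composition with Deep Feature Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies antioxidant proteins from primary sequence alone. Protein
    sequences are encoded as mixed 0-gap and 1-gap dipeptide composition vectors
    (800 dimensions), compressed to a 50-dimensional representation by a
    class-weight-aware deep autoencoder followed by supervised fine-tuning of a
    fully connected head, embedded in two dimensions with t-SNE, and classified
    with a class-weighted linear support vector machine. Includes a synthetic
    sequence generator with planted dipeptide biases, a stratified 10-fold
    cross-validation harness with pooled sensitivity, specificity, accuracy, F1
    and Matthews correlation coefficient, and ggplot2 visualisations of
    embeddings and training histories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
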