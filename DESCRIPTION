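Package: quadqsar
Title: Quadratic-Descriptor QSAR Models and Feature-Space Inversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds multi-linear property-prediction models over linear
    graph-theoretic descriptors and their quadratic interaction terms
    (products and complement-products of min-max normalised descriptors),
    with randomized lasso-based and backward-stepwise descriptor reduction
    and a repeated 5-fold cross-validation scoring protocol. A
    mixed-integer formulation embeds the trained prediction function --
    linearising each quadratic term with a p-bit binary-expansion product
    gadget -- to infer descriptor vectors whose predicted property falls
    in a target range, including a grid-based search for neighbouring
    solutions. Ships a synthetic-data generator with planted sparse
    linear-plus-quadratic responses so the whole pipeline is testable
    without external datasets.
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
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    scales,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
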