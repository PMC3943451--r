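Package: healthscales
Title: Biological and Lived Health Scales from Ordinal Survey Items
Version: 0.1.0
Authors@R:
    person("EDAD", "Scales Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Builds summary scales of biological health (capacity) and lived
    health (performance) from ordinal disability-survey items using Samejima's
    graded response model with marginal maximum likelihood (EM) calibration,
    screens the item response theory assumptions (unidimensionality, local
    independence, monotonicity), detects differential item functioning with
    iterative hybrid ordinal logistic regression and a McFadden pseudo
    R-squared criterion, calibrates flagged items separately per group, and
    compares the resulting 0-100 scores as predictors of self-reported
    general health with a random-forest regression and Strobl-style
    conditional permutation importance. A synthetic survey generator emulates
    the structure of a national disability survey (two populations, correlated
    latent traits, assistance-dependent missingness) so the whole pipeline is
    testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
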