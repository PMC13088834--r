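Package: emanova
Title: Ensemble Distance-Based Association Testing for Microbiome Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Distance-based testing of the association between microbial
    community composition and covariates of interest, adjusting for
    confounders. Base statistics are traces of projection contrasts against
    powers of a centered, positive semi-definite kernel built from weighted
    UniFrac, unweighted UniFrac, or Bray-Curtis distances. P-values are
    obtained analytically by matching the exact first three moments of the
    permutation null distribution to a Pearson type III law, and an ensemble
    p-value across distances and kernel powers is formed with the Cauchy
    combination method, so no permutation sampling is needed anywhere.
    Includes a synthetic-data generator for sparse compositional tables with
    random phylogenies, replicate runners for type I error and power studies,
    and exhaustive and Monte Carlo permutation oracles for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
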