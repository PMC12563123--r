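Package: hydroinfo
Title: Information-Theoretic Descriptors for Water Force-Field Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates rigid three-site water models (TIP3P, SPC, SPCE) with
    information-theoretic descriptors of surrogate electron densities.
    Builds analytic Gaussian-mixture densities from force-field geometries
    and charges, forms their momentum-space conjugates, and integrates
    Shannon entropy, Fisher information, disequilibrium, and the LMC and
    Fisher-Shannon complexities by adaptive tensor-product quadrature.
    Includes Sevick oxygen-oxygen cluster identification for coordinate
    frames, a statistics suite (Shapiro-Wilk, Filliben probability plots,
    Welch's t-test), and a pipeline that turns seeded synthetic ensembles
    into per-frame descriptor tables, normality screens, Welch matrices,
    and cluster-size scaling reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
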