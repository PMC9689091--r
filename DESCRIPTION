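Package: metaboga
Title: Genetic-Algorithm Selection of Metabolite Panels for Disease Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Wrapper feature selection for untargeted metabolomics feature
    tables. Implements probabilistic quotient normalization with inclusion
    filtering, a GALGO-style genetic algorithm that evolves fixed-size
    metabolite subsets toward maximal cross-validated classification accuracy
    under three classifier fitness functions (k-nearest neighbours, nearest
    centroid, radial-kernel support vector machine), forward selection of
    compact models from the resulting gene ranks, and intersection reports
    that nominate metabolites recurring across classifiers and across pairwise
    disease-stage comparisons as progression biomarker candidates. Ships a
    synthetic lipidomics data generator with planted discriminative features
    so the whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
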