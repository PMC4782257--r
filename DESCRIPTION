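Package: morpholab
Title: Phylogenetic Morphometrics of Skull Shape Diversity and Lability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-morphometrics pipeline for asking whether more
    diverse parts of a skull are also more capable of evolutionary change.
    Provides Generalized Procrustes Analysis with bending-energy sliding of
    semi-landmarks, phylogenetically informed multivariate allometry tests
    with permutation inference, evolutionary-model fitting on shape data
    (Brownian motion, Ornstein-Uhlenbeck, early burst, Pagel's delta, and a
    combined delta plus OU model) with AIC selection and the pooled
    multivariate rate sigma^2_mult, ancestral shape reconstruction, and
    random-skewers lability indexes (respondability, evolvability,
    flexibility) computed from mean-standardized P-matrices. Includes a
    synthetic-data generator (pure-birth trees, multivariate trait evolution
    mapped onto landmark templates, TPS file output) so the whole pipeline is
    testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
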