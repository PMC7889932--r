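Package: netage
Title: Network Age: Developmental Descriptors from Temporal Social
    Networks in Honey Bee Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes "network age", a one-dimensional daily descriptor of
    an individual's role in an animal society, from multimodal
    social-interaction networks. Daily affinity matrices (proximity counts,
    trophallaxis counts, spatial-distance similarities, and directed
    movement-effect networks) are rank-transformed, embedded with spectral
    and bispectral decompositions, sign-aligned across days, and projected
    with canonical correlation analysis against a nest-area task descriptor.
    Includes a Bayesian changepoint model for death-date estimation from
    daily detection counts, circadian rhythmicity and velocity metrics,
    task-prediction models with McFadden's pseudo R2 and bootstrap model
    comparison, developmental-trajectory clustering, a future-prediction
    protocol with a persistence null, and a synthetic colony simulator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    mgcv,
    nnet,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
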