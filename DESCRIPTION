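Package: biointerest
Title: Drivers of Scientific and Societal Interest in Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, testable pipeline for quantifying and explaining
    scientific (publication counts) and societal (encyclopedia pageview
    counts) interest in species across the Tree of Life. Provides stratified
    taxonomic sampling from a GBIF-style backbone, construction of
    species-level trait and cultural covariates including a great-circle
    occurrence-dispersion range statistic, negative-binomial and
    zero-inflated negative-binomial mixed count models with nested taxonomic
    and crossed biogeographic random intercepts (Laplace approximation),
    overdispersion/zero-inflation/collinearity diagnostics, marginal and
    conditional R-squared with variance partitioning into species-level
    versus cultural components, and a penalized-spline residual score of
    scientific-versus-societal imbalance. A seeded synthetic-data generator
    with known ground truth stands in for harvested bibliometric,
    encyclopedia, and occurrence data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    Matrix,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
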