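Package: admtools
Title: Association Distribution Modelling for Compositional Ecological Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the spatial and temporal distribution of pairwise
    ecological associations rather than individual species. Computes the
    proportionality metric rho between taxa in compositional abundance
    tables (after occurrence filtering, multiplicative zero imputation and
    centred log-ratio transformation), decomposes each association into
    per-sample local contributions alpha, learns classification (cADM) and
    regression (rADM) models of these signals from environmental
    predictors, projects them onto gridded environmental fields in present
    and future climates, reconstructs projected association strengths
    rho*, clusters projections into biogeographic signatures, summarizes
    association-graph topology, and classifies associations into climate
    response groups from temporal slopes. Includes a synthetic-data
    generator with planted associations along environmental gradients so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    xgboost,
    e1071,
    igraph,
    cluster,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ncdf4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
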