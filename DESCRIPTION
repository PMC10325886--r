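Package: biodivedm
Title: Dynamics-Based Characterization and Classification of Biodiversity Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes classical biodiversity indicators (richness, abundance,
    diversity, evenness, taxonomic diversity, community-weighted latitudinal
    centre of distribution) from community abundance time series, measures each
    indicator's environmental responsiveness with sliding-window simplex
    projection mutual prediction, diagnoses determinism and nonlinearity via
    self-prediction and the regularized S-map, and classifies indicators by
    Ward clustering of their mutual-prediction matrices with SIMPROF
    permutation tests. Includes a multispecies Ricker community simulator with
    seasonal forcing and a mid-series warming regime shift for method
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
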