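Package: yieldgapr
Title: County-Level Grain Yield-Gap Analysis with Spatial Statistics and
    Random-Forest Determinant Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates county-level grain yield gaps from gridded light,
    temperature, water and soil restrictions using a step-wise
    agro-ecological revision model, tracks yield-gap change across epochs,
    detects spatial clustering with Getis-Ord Gi* hot-spot analysis and
    bivariate Moran's I / LISA permutation inference, ranks 27 candidate
    determinants of yield-gap change with random-forest importance, and
    screens counties with high improvement capacity under an
    incremental-production scenario. Ships a seeded synthetic county
    landscape generator with known ground truth so the whole pipeline is
    testable end to end without proprietary provincial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
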