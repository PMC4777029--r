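Package: latticemoran
Title: Global and Local Moran Statistics for Lattice Data with a
    Bivariate Spatial Correlation Extension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial autocorrelation analysis for areal (lattice) data:
    binary queen-contiguity spatial weights with GAL file input/output,
    rank-based (Blom) normal-score transformation, global Moran's I with
    normal-theory and permutation inference, local Moran (LISA) hot-spot
    detection with conditional Monte-Carlo p-values, and Wartenberg-style
    bivariate spatial cross-correlation with Monte-Carlo significance
    testing.  Includes a simultaneous-autoregressive (SAR) lattice field
    simulator for power and type-I-error studies, quartile choropleth
    classification, and a packaged fixture reproducing a published
    analysis of unemployment and chronic-illness rates across the 18
    governorates of Iraq (2007 household socio-economic survey).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    e1071,
    withr
Config/testthat/edition: 3
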