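Package: hvhforest
Title: Height Variation Hypothesis Analysis for Forest Canopy Height Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test the Height Variation Hypothesis (HVH): compute
    height-heterogeneity indices (Rao's quadratic entropy, coefficient of
    variation, Shannon's H, Simpson's D) from canopy height model rasters over
    square field plots, relate them to in-situ tree species diversity through
    single and multiple linear regression with repeated k-fold
    cross-validation, validate one canopy height model against a reference,
    and map heterogeneity with a moving-window Rao's Q. A synthetic forest
    scene simulator with a tunable coupling between vertical structure and
    species diversity makes the full workflow runnable without external data.
    Rasters are exchanged as plain-text ESRI ASCII grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
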