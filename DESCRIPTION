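Package: climspace
Title: Coupled Climate-Space and Somatic Growth Projections for River Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting how climate change shifts both the potential
    distribution ("climate space") and the somatic growth of temperate river
    fishes. Implements AUC-weighted multi-algorithm ensemble distribution
    models, scale back-calculation and two-parameter von Bertalanffy growth
    fitting, GCV-weighted climate models of asymptotic length and growth rate,
    range-shift statistics (cell counts, centroid displacement, coordinate
    t-tests), and the coupling of the two model streams by linear regression.
    Includes a synthetic-data generator emulating gridded bioclimatic surfaces,
    logistic climate-niche occupancy and temperature-size-rule growth data so
    the whole workflow runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
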