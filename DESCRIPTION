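Package: lrcfit
Title: Mechanistic Fitting of Photosynthetic Light-Response Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits photosynthetic light-response curves with three model
    families: the rectangular hyperbola, the non-rectangular hyperbola, and
    a mechanistic rational-function model with an explicit photoinhibition
    term. Provides closed-form derived traits (maximum net photosynthetic
    rate, saturation and compensation irradiances, maximum electron
    transport rate, apparent electron requirement), AIC/R-squared/MAE model
    comparison against empirical trait estimates, light responses of
    derived efficiency channels (light-use, carboxylation and water-use
    efficiency, non-photochemical quenching, PSII quantum efficiency),
    light-harvesting pigment photophysics (pigment pool size, effective
    absorption cross-section, excited-state pool), and a replicate
    structured synthetic light-curve generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
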