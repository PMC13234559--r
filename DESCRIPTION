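Package: baciR
Title: Spatial Before-After-Control-Impact Evaluation with Statistical Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counterfactual impact evaluation of ecosystem conservation and
    restoration interventions on a raster grid. Defines pixel-based impact and
    candidate-control units from intervention polygons (with neighbourhood
    buffers, exclusion zones and seeded subsampling), derives and screens
    matching covariates (terrain derivatives, distances to linear features,
    land cover, variance inflation factors), matches control to impact units
    by propensity-score or Mahalanobis nearest-neighbour or exact matching
    with balance diagnostics, summarises yearly vegetation-index time series
    into mean and trend metrics with cloud-aware median compositing, and
    estimates the before-after-control-impact (BACI) difference-in-difference
    contrast with a one-sample t-test on per-impact-unit contrasts. Includes a
    synthetic-landscape generator with known ground truth so the whole
    pipeline runs and tests offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
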