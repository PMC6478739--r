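Package: sspforest
Title: Spatially Explicit Forest Cover Change Scenarios and Aboveground
    Carbon Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates spatially explicit forest cover change scenarios
    driven by shared socioeconomic pathway (SSP) forest-area projections.
    Reclassifies categorical land cover to forest/non-forest, converts
    regional net-change projections into per-country pixel demands via
    historical change shares, models per-pixel transition potentials with
    a multi-layer perceptron over seven spatial driver grids, validates
    models with the Skill Measure, allocates demanded change greedily to
    the highest-potential pixels, and projects aboveground forest carbon
    stock changes with a forest-age/carbon-sequestration-rate growth
    model, reported as zonal ledgers (country, province, forest class,
    intact forest, protected area).  Ships a seedable synthetic landscape
    generator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
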