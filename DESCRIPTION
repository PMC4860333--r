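Package: hornwalk
Title: Individual-Based Bighorn Sheep Movement Model for Landscape Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based model of bighorn sheep (Ovis canadensis)
    movement on rasterized landscapes. Agents perform a pseudo-biased random
    walk over a grid of slope, crown cover, water and road layers, preferring
    cells near steep escape terrain and avoiding barriers. Aggregating many
    simulated trajectories yields relative frequency-of-use maps that estimate
    landscape connectivity, support counterfactual management scenarios
    (fire-restored canopy, permeable roads) and rank candidate road-crossing
    sites. Includes a synthetic landscape generator, a validation metric based
    on occurrence-point coverage, and a parameter sweep utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    ggplot2,
    generics,
    yaml,
    EBImage,
    rlang,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
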