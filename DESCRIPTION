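Package: pacarbon
Title: Counterfactual Carbon Accounting for Protected Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the "carbon effectiveness" of protected areas by
    matching protected 1-km cells to ecologically similar unprotected
    counterfactual cells, comparing lidar-derived aboveground carbon between
    the two, attributing differences to avoided deforestation or degradation
    via forest-loss records, and aggregating additionally preserved carbon
    with uncertainty to country, continent, biome and global scales. A
    synthetic-landscape generator with known ground truth (confounded
    protected-area placement, along-track lidar footprint sampling,
    status-dependent forest-loss rates) makes every pipeline stage testable
    by parameter recovery without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
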