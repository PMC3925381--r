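Package: eccniche
Title: Ecomorph Community Completeness from Presence-Background Niche Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits maximum-entropy-style presence-background ecological niche
    models per ecomorph per island, combines the rescaled suitability maps
    into ecomorph community completeness (ECC) surfaces, quantifies
    cross-island niche overlap with Schoener's D, tests ECC-environment
    correlations on decorrelated k-means subsamples with permutation
    p-values, competes candidate environmental regression models via AICc
    with model averaging, and relates each ecomorph's elevational constraint
    to its body-mass rank. Includes a synthetic island-landscape generator
    with known ground truth so the whole pipeline is testable end to end,
    plus readers and writers for ESRI ASCII grids, occurrence CSVs, YAML
    configs and JSON summaries, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
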