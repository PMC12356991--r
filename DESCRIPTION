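Package: mammoiq
Title: Task-Based Mammography Image Quality from Model-Observer Detectability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assigns raw ("for processing") digital mammograms a ground-truth
    microcalcification-detectability score using a channelized Hotelling
    observer with Laguerre-Gauss channels on hybrid (lesion-inserted) regions
    of interest, then predicts that score from radiomic features using
    correlation-based feature subset selection (CFS) inside a nested
    cross-validation and a multilayer-perceptron regressor.  Includes a
    synthetic raw-mammogram generator (power-law parenchymal texture,
    signal-dependent quantum noise, two detector presets), dose-reduction and
    motion-blur degradation models, a native radiomic feature extractor
    (filter bank plus first-order and gray-level texture-matrix classes), and
    an end-to-end, seed-reproducible experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
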