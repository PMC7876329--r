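Package: floracount
Title: Counting Flowering Plants in Aerial Imagery by Density-Map Regression
Version: 0.1.0
Authors@R:
    person("Field", "Phenotyping Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for counting objects in RGB field imagery by density
    estimation. Converts point annotations into Gaussian density targets,
    trains a fully convolutional encoder-decoder (U-net style) density
    regressor, produces counts by integrating predicted density maps,
    extracts discrete peak localizations for annotation workflows, ranks
    unlabeled samples for active learning by the integrated-count versus
    peak-count deficit, and runs tiled inference with density overlays over
    large orthomosaics. Includes a synthetic field-image generator with
    known ground truth so the whole pipeline is testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
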