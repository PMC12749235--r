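Package: paintcrypt
Title: DNA Origami Cryptography Readout from DNA-PAINT Localizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encode text messages as docking-site patterns on 2D and 3D DNA
    origami, simulate DNA-PAINT single-molecule localization data with
    realistic detection efficiency, localization noise and particle-level
    distortions, and decode the patterns back with an unsupervised pipeline:
    k-means clustering with elbow selection of the cluster count, cluster
    filtering, weighted template registration with anisotropic scaling
    (shear) in 2D and a z-scale/rotation grid search in 3D, bit extraction
    with redundancy collapse, and accuracy, peak-ratio and
    detection-efficiency reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
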