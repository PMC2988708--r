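Package: aeroscan
Title: Blip Extraction and Track Building for Surveillance-Radar Aeroecology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless processing toolkit for digitized marine surveillance-radar
    scans used in aeroecology. Detects putative biological targets ("blips") in
    polar scan matrices with an adaptive background model and z-score
    thresholding, links blips across scans into tracks with nearest-neighbour
    and multiframe-correspondence algorithms, archives scans and blips in
    compressed self-describing text containers, exports delimited summaries,
    and simulates seeded synthetic scan sequences with known ground truth for
    algorithm validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
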