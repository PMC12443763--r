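Package: empdsr
Title: Size-Dependent Lung Retention of Elongate Mineral Particles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the size-dependent deposition and retention of
    elongate mineral particles (EMPs) in human lungs. Reconstructs fiber-level
    datasets from binned length-by-width frequency matrices by Monte Carlo
    sampling with truncated log-normal within-bin distributions, computes the
    deposition selection ratio (DSR, the ratio of a size bin's frequency in
    lung burden to its frequency in the airborne exposure), classifies particle
    populations as asbestiform or non-asbestiform from the criteria fraction
    and Pearson index, fits log-log regressions of DSR on particle length and
    width, fits a mesothelioma-potency model from average DSR and
    biopersistence, and compares observed DSR against packaged MPPD pulmonary
    deposition rates. Ships the Pooley-Clark amosite and crocidolite lung
    burden and exposure frequency tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
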