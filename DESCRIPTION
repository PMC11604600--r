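Package: coccotraits
Title: Size and Biogeochemical Trait Reconstruction for Calcareous Nannoplankton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs cell-size, organic-carbon (POC) and inorganic-carbon
    (PIC) trait distributions of fossil calcareous nannoplankton from coccolith
    and coccosphere morphometrics, and aggregates them into community-level
    size structure, size-class carbon partitioning and community PIC:POC
    through time. Implements the placolith coccosphere-geometry allometry
    (log-log regression of coccolith length on cell surface area per
    coccolith), a coverage-factor parameterization for nannolith and
    holococcolith taxa, calcite shape-factor PIC estimation, likelihood
    weighting of coccolith-length by coccoliths-per-cell combinations, and an
    assemblage pipeline (relative abundances with confidence intervals,
    moving-average smoothing, coccolith-to-cell conversion, community
    stacking and standing-stock scenarios). Includes a synthetic-data
    generator with recorded ground truth so every stage is testable without
    the original microscopy datasets.
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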