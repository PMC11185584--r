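Package: prmflow
Title: Building and Scheduling Highly Multiplex Parallel Reaction
    Monitoring Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for turning data-independent-acquisition (DIA)
    chromatogram libraries into scheduled parallel reaction monitoring
    (PRM) assays on duty-cycle constrained instruments. Provides
    precursor quality filtering (area, peak width, co-eluting
    interference-free transition counts), retention-time window
    scheduling under a points-per-peak duty-cycle model with
    multi-injection splitting, a simulation of real-time adaptive
    retention-time alignment against a compressed binned DIA reference
    map, and matrix-matched calibration-curve figures of merit
    (coefficient of variation, accuracy ratios, limits of detection and
    quantification, transition-subset optimization). A synthetic-data
    generator produces chromatogram libraries, dilution series and
    retention-time-warped runs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
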