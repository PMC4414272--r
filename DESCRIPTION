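Package: ublcleave
Title: Product-Inhibited Cleavage Kinetics and Assay Quantification for
    UBL-Tag Proteases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and estimation pipeline for proteolytic removal of
    ubiquitin-like-protein (UBL) tags, as performed with Atg4-family,
    SUMO- and NEDD8-specific proteases. Implements a product-inhibited
    extension of Michaelis-Menten kinetics, its single-exponential
    progress-curve approximation under the equal-affinity assumption, and
    apparent first-order cleavage-rate estimators from single time points
    or full time courses. Also provides gel-densitometry calibration
    against mixed cleavage standards, titration-endpoint detection
    (minimal protease concentration for near-complete cleavage),
    protease-by-substrate cross-reactivity classification with
    orthogonality calls, and seeded synthetic-data generators that emulate
    each assay for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    igraph,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
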