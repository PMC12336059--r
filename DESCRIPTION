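Package: cvrquant
Title: Quantification of Cerebrovascular Reactivity from CO2-Challenge MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end quantification of cerebrovascular reactivity (CVR)
    from hypercapnia-challenge MRI: end-tidal CO2 extraction from raw
    capnograph traces, voxelwise BOLD-CVR mapping via a shifted end-tidal CO2
    regressor in a general linear model, phase-contrast flow quantification
    with venc unwrapping and unit-mass CBF conversion, venous oximetry from
    T2-relaxation-under-spin-tagging (TRUST) series, a Davis-type forward
    model of the hypercapnic BOLD response, and the group statistics of a
    two-group pre/post-caffeine crossover design. Includes a synthetic-data
    generator that renders every raw input (capnograph traces, 4D BOLD
    series, phase-contrast image pairs, TRUST label/control series, full
    cohorts) from explicit ground truth so the whole pipeline is testable by
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    minpack.lm,
    lme4,
    lmerTest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
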