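Package: replifoci
Title: Replisome and Chromosomal Locus Dynamics from Single-Cell Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the spatial relationship between the
    bacterial replisome and fluorescently labelled chromosomal loci in
    time-lapse single-cell (mother-machine) experiments. Implements
    cell-internal coordinate projection and cell-cycle-binned location
    histograms, frame-to-frame focus linking with replication-initiation
    detection, initiation-aligned root-mean-squared-displacement analysis
    with net-drift subtraction, one-second displacement statistics binned
    by cell area and intracellular position, two-channel landmark
    registration and replisome-locus distance estimation, and the
    exponential replication-size model A(alpha) = A_init * exp(mu * C *
    alpha). A synthetic lineage generator with confined (mean-reverting)
    replisome motion and state-dependent locus dynamics provides ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
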