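Package: colonyphen
Title: Phenological Occupancy and Windchill-Density Models for Remote
    Colony Censusing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic tools for estimating breeding pairs, breeding
    success and phenological event dates of Antarctic seabird colonies from
    sparse late-season imagery. Implements a meteorology-driven huddling
    density ("windchill") model that converts colony area to individual
    counts, a Gaussian event-mixture phenological occupancy model of the
    breeding season, affine-invariant ensemble MCMC fitting of both models
    (full 14-parameter mode for dense ground counts and a constrained
    2-parameter mode for sparse satellite-derived counts), solar geometry to
    anchor arrival dates to the first sunrise after midwinter, a
    synthetic-season generator with known ground truth, and an end-to-end
    area-to-abundance pipeline.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
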