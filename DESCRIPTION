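Package: mechanoephys
Title: Analysis of Combined Atomic Force Microscopy and High-Density
    Microelectrode Array Experiments on Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mechano-electrophysiology experiments that combine
    atomic force microscopy (AFM), high-density microelectrode arrays
    (HD-MEA) and fluorescence imaging of neurons. Provides Hertz
    contact-model fitting of AFM force curves with baseline and
    contact-point detection, spike-train firing-rate and network-burst
    analysis around mechanical stimuli, extracellular waveform-feature
    extraction across electrode grids, calcium-transient detection with
    decay-constant fitting, TTL time-base alignment across instruments,
    nonparametric statistics with exact small-sample p-values, and a
    seeded synthetic-data generator that emulates the synchronized
    multimodal data streams with a ground-truth manifest so every
    analysis stage is verifiable by parameter recovery.
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
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
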