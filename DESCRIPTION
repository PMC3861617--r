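Package: wntwave
Title: Kinetics of Wnt-Evoked Calcium Transients and Beta-Catenin Nuclear Translocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of ratiometric (Fluo-4/FuraRed) intracellular
    calcium imaging: single-Gaussian waveform fitting with 10%/90% amplitude
    thresholding to extract rise, dwell and fall time constants; kinetic
    classification of Wnt ligands by dwell time; negative-cooperativity
    (first-order decay) and Michaelis-Menten dose-response fits of dwell time
    versus ligand concentration; calcium wave-front speed estimation and
    cytosol-to-nucleus onset lags; per-cell Pearson colocalization of nuclear
    translocation with Mann-Whitney group comparison; and scratch-wound closure
    rate regression with an F test on slopes. Includes a synthetic-data
    generator producing traces, images and wound tables with known ground truth.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
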