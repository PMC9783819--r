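Package: ppchron
Title: Time-Series Homeostasis Analysis of 6-Pentyl-alpha-Pyrone Emission
    Chronograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing volatile organic compound emission monitored
    by ambient ionization mass spectrometry as a physiological time series.
    Builds extracted-ion chronograms for a target ion (by default the
    protonated 6-pentyl-alpha-pyrone ion at m/z 167.1), aggregates
    technical and biological replicates into mean and standard-deviation
    series, and computes a homeostasis descriptor suite: moment-based
    skewness and excess kurtosis, the autocorrelation function, Poincare
    plot SD1/SD2 descriptors, value histograms, and area-under-curve
    production totals.  A calibrated stochastic generator emulates
    background, constitutive fungal, and plant-fungal interaction emission
    regimes (circadian envelope, Poisson-gamma bursts, AR(1) instrument
    noise) so the full pipeline can be exercised and validated without
    instrument data.  An interpretive layer classifies a signal as
    background, physiological, or stabilized from its descriptors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    e1071,
    ggplot2,
    mzR,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
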