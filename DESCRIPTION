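Package: dcpas
Title: Dual-Comb Photoacoustic Spectroscopy Simulation and Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale simulator and processing pipeline for dual-comb
    photoacoustic spectroscopy (DCPAS). Models a pair of frequency combs and
    the one-to-one mapping between optical comb-tooth frequencies and
    radio-frequency beat notes, synthesizes multi-heterodyne photoacoustic
    interferograms from analytic sample absorption spectra through a
    transducer/amplifier detection chain with additive detector noise, and
    recovers the optical absorption spectrum via the apodize / Fourier
    transform / frequency-map / normalize chain. Includes signal-to-noise
    analysis tools: time-domain and spectral SNR estimators, square-root
    averaging-time and power-linearity fits, and an acquisition-time scaling
    calculator for repetition rate, absorbance, power and noise factors.
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
    withr,
    yaml
Config/testthat/edition: 3
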