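Package: spaintr
Title: Spectrally-Resolved PAINT Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for spectrally-resolved PAINT
    (sPAINT) single-molecule localization microscopy, in which a blazed
    transmission grating projects both the undiffracted (spatial) and
    first-order (spectral) image of each emitter onto one EMCCD detector.
    Provides a physics-based forward simulator of dual-order camera frames
    with exact ground truth (grating optics, PAINT binding kinetics,
    EMCCD noise), spot detection and 2D Gaussian fitting with photon
    conversion, transmission-grating spectral calibration by multiple
    linear regression with field-aberration correction, per-localization
    emission-wavelength assignment, DBSCAN clustering of localizations
    into structures, binding-kinetics statistics, super-resolved density
    and false-coloured hydrophobicity rendering, Nadaraya-Watson
    spatio-temporal wavelength maps, and empirical localization-precision
    analysis versus photon count.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
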