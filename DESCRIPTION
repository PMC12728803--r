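Package: lfpclean
Title: Preprocessing of Chronically Sensed Deep-Brain Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cleaning and spectrally characterising local field
    potentials (LFPs) streamed from implanted deep-brain stimulation devices.
    Implements cardiac QRS artifact removal by Hanning-tapered template
    subtraction with cross-hemisphere event transfer, Welch and multitaper
    power spectral density estimation with explicit window-length and
    taper-count arithmetic, Grubbs-test rejection of nonstationary spectrogram
    windows (with a PCA-based alternative background estimate), and two-pass
    aperiodic 1/f detrending of power spectra. Ships a ground-truth-annotated
    synthetic LFP generator so the whole pipeline is testable without patient
    recordings, plus a CSV + JSON recording format and a command-line
    pipeline driver.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
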