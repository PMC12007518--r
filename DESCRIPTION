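Package: betaharmonics
Title: Distinguishing Genuine Beta-Band Rhythms from Alpha-Band Harmonics in EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether beta-band (16-30 Hz) spectral peaks in
    resting-state EEG reflect genuine beta rhythms or harmonics of nonsinusoidal
    alpha-band rhythms. Implements percentile spectra (fixed-length segments
    sorted into groups by band power), 1/f aperiodic fitting and correction,
    Spearman rank correlation of corrected alpha- and beta-power across groups,
    a harmonic classification rule based on the beta/alpha peak-frequency ratio
    with a one-frequency-bin tolerance and an SNR gate, and spatio-spectral
    decomposition (SSD) for extracting the component with the highest alpha-band
    signal-to-noise ratio from multichannel recordings. A synthetic EEG
    generator produces nonsinusoidal rhythms with phase-locked harmonics,
    broadband genuine beta rhythms, 1/f background noise, and controlled
    cross-band amplitude-coupling regimes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ggplot2,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
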