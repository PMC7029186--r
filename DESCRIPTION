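Package: swimrhythm
Title: Rhythmicity Analysis of Larval Zebrafish Fictive Swimming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the 20-40 Hz tail-beat rhythm of developing
    zebrafish from ventral-root recordings and high-speed video. Implements
    the Peak_20-40 autocorrelation rhythmicity statistic (quadratic fit of
    the epoch autocorrelation on the 20-50 ms lag window, peak acceptance in
    the 25-50 ms range), episode detection and epoch extraction, per-recording
    rhythm scores, strychnine attenuation and the rejection rule, short-time
    Fourier spectrograms, a tail-kinematics pipeline (silhouette to midline
    to 30-segment bend angles to per-segment spectra), a driven damped
    harmonic oscillator model of the pacemaker-to-network-oscillator
    transition, the associated group statistics, and seeded synthetic-data
    generators that emulate fictive swimming recordings, IPSC event trains
    and swimming-fish videos so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
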