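Package: gammashape
Title: Shape Analysis of Gamma Oscillations and Wilson-Cowan Rate-Model Regimes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the non-sinusoidal ("arch") shape of cortical gamma
    oscillations through the phase relationship between gamma (30-70 Hz) and
    its first harmonic: multitaper spectral estimation with DPSS tapers,
    gamma/harmonic peak detection and peak-frequency-ratio statistics,
    zero-phase Butterworth band extraction with Hilbert instantaneous phase,
    the wrapped 2*phi_gamma - phi_harmonic phase-difference statistic, and
    circular summaries (circular mean, von Mises confidence intervals,
    Rayleigh test, mean vector strength). Includes forward-Euler simulators
    for two Wilson-Cowan-type rate models of visually induced gamma -- a
    stochastically driven linear three-population model and a two-population
    sigmoidal inhibition-stabilized model -- together with input-drive grid
    scans that locate the operating regimes producing arch-shaped gamma
    (phase difference near 180 degrees), and a synthetic LFP trial-set
    generator for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
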