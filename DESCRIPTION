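Package: radarecg
Title: ECG Reconstruction from Millimeter-Wave Radar Chest Vibration Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A simulation, preprocessing and modelling stack for contactless
    cardiac monitoring with continuous-wave millimeter-wave radar. Provides a
    physics-based simulator of quadrature radar echoes from chest-wall motion
    coupled to a synthetic ECG, arctangent demodulation and phase unwrapping,
    respiratory suppression by maximal-overlap discrete wavelet transform with
    adaptive Kalman smoothing, an encoder-decoder neural network (parallel
    multi-scale convolutional and self-attention encoder, temporal
    convolutional decoder with spectral attention) that maps radar-derived
    cardiac mechanical motion to ECG waveforms, subject-disjoint
    cross-validated training, and morphological plus wave-localization
    evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
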