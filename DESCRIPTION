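Package: vasomet
Title: Joint Wavelet Analysis of Skin Vasomotion and Metabolic Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint spectral analysis of microvascular blood-flow
    oscillations (laser-Doppler flowmetry, LDF) and skin metabolic oscillations
    measured by NAD(P)H autofluorescence spectroscopy. Extracts fluorophore
    peak amplitudes, the optical redox ratio and elastin-normalised NAD(P)H
    from discrete emission spectra; reconstructs uniformly sampled biomarker
    signals by piecewise cubic spline interpolation; computes Morlet
    continuous wavelet transforms with cone-of-influence masking and
    time-averaged spectra on a logarithmic frequency grid; summarises named
    physiological frequency bands (cardiac, respiratory, myogenic, neurogenic,
    endothelial NO-dependent, EDHF, and slow metabolic oscillators) by
    relative wavelet energy, amplitude and peak frequency; quantifies wavelet
    phase coherence between simultaneously recorded signals; estimates tissue
    oxygen saturation by Beer-Lambert haemoglobin unmixing; and provides the
    group-comparison and correlation statistics for baseline versus
    vasoconstrictor-stimulus designs. A synthetic-data generator with known
    ground truth (band-limited phase-diffused oscillators, 1/f noise,
    controllable metabolic-vascular phase coupling) supports validation of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
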