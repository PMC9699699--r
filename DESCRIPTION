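Package: catrace
Title: Chronic Calcium-Imaging Quantification for Cultured Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantification pipeline for longitudinal (days-to-weeks)
    calcium imaging of cultured cortical neurons expressing genetically
    encoded calcium indicators. Covers dF/F0 trace conditioning with
    background subtraction and neuropil correction, spontaneous event
    detection by the three-standard-deviations rule with waveform metrics
    (amplitude, FWHM, 50 percent rise and decay times), network synchrony
    as the mean pairwise Spearman rank correlation per field of view,
    one-sided FFT amplitude spectra with ultra-slow/slow/fast band
    fractions, image morphometry (nuclear-to-cytosolic intensity ratio
    with nuclear-filling classification, soma area, skeleton-based
    neurite length, Sholl profiles, image contrast), and longitudinal
    stage statistics (temporal profiles, growth rates, profile
    correlations, group comparisons). A synthetic-data generator with
    per-stage presets emulates the developmental and probe-toxicity
    regimes so every stage of the pipeline is verifiable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
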