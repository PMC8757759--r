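Package: gridEMG
Title: Spatial Analysis of High-Density Surface EMG Grid Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for spatial analysis of high-density surface
    electromyography (HDsEMG) recorded from two-dimensional electrode
    grids. Provides S4 containers for grid geometry, multichannel
    recordings and RMS activation maps; preprocessing (zero-phase
    band-pass filtering, monopolar to single-differential derivation,
    contraction segmentation, windowed RMS mapping); scalar map features
    (intensity, differential intensity, modified entropy, coefficient of
    variation, mean RMS, median frequency); point-based and
    trajectory-based centre-of-gravity estimation with agreement
    analysis; group-level statistics (normality screening, paired
    t-tests with Bonferroni correction, Pearson correlation); a
    synthetic grid-EMG generator with known spatial ground truth; and a
    reproducible end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
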