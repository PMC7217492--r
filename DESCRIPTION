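Package: circaquant
Title: Quantitative Analysis of Circadian Live-Cell Imaging, Photobleaching
    and Fluorescence Correlation Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the dynamics of fluorescently tagged clock
    proteins in live-imaging experiments. Provides single-cell circadian
    rhythmicity calling from fluorescence or bioluminescence tracks (a-trous
    band-pass filtering, power-spectrum and autocorrelation classification,
    damped-cosine fits with relative amplitude error), one-phase decay fits
    for protein and mRNA half-life estimation (including 2^-ddCt
    normalisation), FRAP and FLIP photokinetics (two-component-plus-immobile
    recovery models), fluorescence correlation spectroscopy fitting
    (one-component triplet-state diffusion model) with conversion to
    diffusion coefficients, molar concentrations and molecules per nucleus,
    non-parametric actigraphy statistics (intra-daily variability,
    inter-daily stability, chi-square periodogram, activity onset and phase
    angle of entrainment), and image-level colocalization and spectral
    linear-unmixing metrics. A synthetic-data module generates every input
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    pracma,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Software, TimeCourse, CellBiology, Visualization
RoxygenNote: 7.3.3
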