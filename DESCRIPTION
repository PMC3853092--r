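Package: neuroHCS
Title: Phenotypic Profiling of Multi-Neuron High-Content Screening Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end analysis of multi-neuron fluorescence micrographs from
    high-content screens. Segments somata and neurites with a four-parameter
    morphological pipeline, skeletonizes neurites and detects attachment,
    ending and branching landmarks to build a 13-feature neuromorphology
    descriptor; computes generic shape and texture descriptor banks (Zernike,
    Legendre and Tchebichef moments, generic Fourier, Haralick co-occurrence
    statistics, Gabor filters, Daubechies-4 wavelet energies); characterizes
    dose-response with Bartlett-gated standard or Welch one-way ANOVA, Tukey
    HSD letter displays and linear/quadratic regression on log concentration
    with a 5-percent model-selection rule; and selects minimal discriminative
    feature sets with an inheritable bi-objective genetic algorithm wrapping a
    radial-basis support vector machine. A synthetic-scene generator with
    exact geometric ground truth makes every stage testable without original
    screen images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    e1071,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
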