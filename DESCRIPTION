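Package: otoradiomics
Title: Dual-Center HRCT Radiomics for Middle Ear Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Texture-based radiomics pipeline for discriminating cholesteatoma
    from middle ear inflammation on high-resolution CT, with explicit handling
    of dual-center acquisition differences. Provides a synthetic dual-center
    cohort generator (stationary Gaussian random-field lesions imaged at
    different matrix sizes over a common field of view), circular-ROI gray-level
    normalization and quantization, six classical texture-feature families
    (histogram, gray-level co-occurrence, run-length, absolute gradient, causal
    autoregressive model, Haar wavelet energies), POE+ACC feature selection,
    LDA/k-NN and multi-layer-perceptron classification protocols, and two
    center-effect corrections: image-domain matrix resampling and
    empirical-Bayes (ComBat-style) feature harmonization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    MASS,
    class,
    sva,
    withr,
    pROC
Config/testthat/edition: 3
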