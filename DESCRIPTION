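Package: petresponse
Title: PET/CT Lesion Texture Radiomics and Treatment-Response Classification
Version: 0.1.0
Authors@R: person("IPO Pipeline", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing oncological treatment response from paired
    pre- and post-treatment PET/CT lesion images. Provides synthetic
    lesion-cohort generation, min-max image normalization, 2D region-growing
    segmentation with a relative threshold, a 171-entry texture descriptor
    suite (gray-level histogram moments, GLCM, GLRL, Daubechies-4 wavelet
    subbands, Gabor filter banks, uniform local binary patterns), SMOTE class
    rebalancing, PCA reduction, six classifier families (kNN, one- and
    two-hidden-layer MLPs, LVQ, RBF and probabilistic neural networks)
    evaluated by leave-one-out cross-validation, and the rank-based Friedman /
    Iman-Davenport / Bonferroni-Dunn procedure for comparing classifiers
    across response classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
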