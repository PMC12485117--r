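Package: olfactr
Title: Analysis of Simultaneous Calcium and Neurochemical Odor-Response Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of simultaneously recorded neuronal (calcium)
    and neurochemical (acetylcholine / serotonin) volumetric fluorescence
    imaging during repeated odor presentations in the fly brain. Provides
    sliding-baseline dF/F trace extraction, per-voxel response metrics
    (responsiveness, intensity, phase delay, pulse width, odor tuning),
    region- and voxel-level functional connectivity networks with community
    detection and a dual-channel deflation-ratio complementation statistic,
    multi-tier odor-identity decoding (block-wise PCA + LDA + linear SVM on
    trial trajectories with cross-validation), low-dimensional manifold
    geometry and temporal-stability analysis across recording stages,
    motion-confound controls (motion energy, behavioral PCs, ridge variance
    partitioning, lagged cross-correlation), a Scheirer-Ray-Hare
    nonparametric two-way ANOVA, and a synthetic-data generator that plants
    ground-truth odor ensembles, channel kinetics, session drift and motion
    coupling for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    e1071,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    tiff,
    withr
Config/testthat/edition: 3
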