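Package: hsiPigments
Title: Hyperspectral Inversion of Leaf and Canopy Pigment Content
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating chlorophyll a, chlorophyll b, carotenoid
    and total pigment content of leafy crops from visible/near-infrared
    hyperspectral images. Covers the full leaf-to-canopy workflow:
    white/dark reference reflectance calibration and ENVI cube I/O,
    canopy segmentation and ROI spectral extraction, spectrophotometric
    pigment assays, spectral preprocessing (moving average, standard
    normal variate, first derivative), wavelength selection (CARS, SPA,
    UVE, LARS), calibration/prediction sample partitioning (random,
    Kennard-Stone, SPXY), classical multivariate regressors (PLSR,
    random forest, SVR, extreme learning machine) run over a combination
    grid, a CNN-BiLSTM-multi-head-self-attention spectral regressor with
    an ablation harness, and per-pixel canopy pigment mapping. A synthetic
    spectra generator with known pigment-to-reflectance physics provides
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    MASS,
    mixOmics,
    randomForest,
    e1071,
    jsonlite,
    png,
    S4Vectors,
    SummarizedExperiment
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'bandSelect.R'
    'canopyMap.R'
    'envi-io.R'
    'grid.R'
    'hsiPigments-package.R'
    'hyperCube.R'
    'lpcnet.R'
    'models.R'
    'nn-layers.R'
    'pigmentAssay.R'
    'pipeline.R'
    'pls-engine.R'
    'preprocess.R'
    'splitters.R'
    'synthdata.R'
    'utils.R'
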