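Package: fibromap
Title: Multi-Contrast Quantitative MRI and Histology Mapping of Tumour Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxel-wise quantitative MRI parameter mapping and
    imaging-pathology correlation for endogenous-contrast studies of
    tumour fibrosis. Implements intravoxel incoherent motion (IVIM)
    bi-exponential diffusion fitting with segmented initialisation,
    dual-regime ultrashort-echo T2* relaxometry, variable-flip-angle T1
    mapping with magnetisation-transfer ratio, apparent MT rate and
    B1-insensitive MT saturation, a Markov-chain Monte Carlo robust
    least-squares fitting engine, Lab colour-space histology stain
    quantification with microvessel density, and a cohort statistics
    layer (ROI medians, Dice overlap, log-transformed coefficients of
    variation, Bonferroni-corrected Pearson correlation and partial
    least-squares regression with leave-one-out cross-validation).
    A synthetic phantom, slide and cohort generator makes the whole
    pipeline testable end to end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tools,
    minpack.lm,
    EBImage,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    png
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort-sim.R'
    'dwi.R'
    'engine.R'
    'fibromap-package.R'
    'histology-sim.R'
    'histology.R'
    'mt.R'
    'phantom.R'
    'pipeline.R'
    'stats.R'
    'ute.R'
    'utils.R'
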