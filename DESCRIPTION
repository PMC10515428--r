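Package: bbbomap
Title: Mapping Blood-Brain-Barrier Opening from Delayed-Contrast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies blood-brain-barrier opening (BBBo) from repeated
    post-contrast T1-weighted MRI (delayed-contrast MRI). Normalized
    per-voxel enhancement curves are fitted to a two-exponential kinetic
    model derived from the Tofts two-compartment exchange model; maximal
    signal increase (Dyn), time over threshold (TT) and area over
    threshold (AOT) are extracted from the fitted curves, and voxels are
    classified as BBBo by goodness-of-fit, enhancement and
    connected-cluster-size filters. Includes histogram and
    exponential-distribution analysis of the parameter maps, rigid
    registration of the time series, dose-response IC50 estimation with a
    four-parameter logistic model, tissue-concentration unit conversion,
    tumor volume and growth-rate quantification, and seeded synthetic
    phantom and plate generators providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'bbbomap-package.R'
    'components.R'
    'kinetics.R'
    'mapping.R'
    'distributions.R'
    'efficacy.R'
    'io.R'
    'pharmacology.R'
    'register.R'
    'pipeline.R'
    'synthetic.R'
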