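Package: EmoConn
Title: EEG Band-Power and Connectivity Decoding of Performed Musical Emotions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis pipeline for discriminating emotions expressed
    during music performance from multichannel EEG. Provides a synthetic-EEG
    generator with planted condition effects (band power, inter-region
    coherence, directed lagged coupling), preprocessing into per-band windowed
    observation tensors (region-of-interest averaging, zero-phase FIR
    filtering, 3 s windowing), three feature families (absolute/relative band
    power, magnitude-squared coherence, binarized pairwise Granger causality),
    two statistical feature-selection regimes (baseline t-test then one-way
    ANOVA, or ANOVA only), and one-vs-one RBF support-vector-machine
    evaluation with k-fold cross-validation, accuracy summaries and
    row-normalized confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    signal,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Electrophysiology, Classification, FeatureExtraction
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'EmoConn-package.R'
    'featureSet.R'
    'classify.R'
    'filters.R'
    'syntheticSpec.R'
    'generate.R'
    'studyDesign.R'
    'preprocess.R'
    'granger.R'
    'select.R'
    'io.R'
    'spectra.R'
    'mscFeatures.R'
    'powerFeatures.R'
    'pipeline.R'
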