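Package: dstrfadapt
Title: Dynamic Spectro-Temporal Receptive Fields and Adaptation to Changing
    Background Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying rapid neural
    adaptation to switching background noise with nonlinear auditory encoding
    models. Generates switching-noise spectrogram sessions with ground-truth
    adaptive encoders (static linear, contrast-gain-adaptive,
    noise-band-suppressing, and linear-nonlinear models with Tsodyks-Markram
    short-term plasticity), fits linear STRF, dilated convolutional network,
    and LN+STP encoding models under a leave-one-block-out jackknife, extracts
    the network's instantaneous equivalent linear filter (dynamic STRF) by
    exact input gradients with sign-consistency masking, and quantifies
    adaptive gain control and noise filtering with transition-aligned indices,
    subject-controlled tests, mixed-effects models, and hierarchical
    clustering of electrode populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    lme4,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'methods-show.R'
    'synthgen.R'
    'encoders-strf.R'
    'encoders-cnn.R'
    'encoders-stp.R'
    'jackknife.R'
    'dstrf.R'
    'adapt-metrics.R'
    'popstats.R'
    'pipeline.R'
    'dstrfadapt-package.R'
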