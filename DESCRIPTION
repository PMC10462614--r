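Package: scnnenc
Title: Spiking Convolutional Network Encoding Models for Visual fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Voxel-wise neural encoding of visual stimuli with a spiking
    convolutional feature extractor. Images are filtered with ON/OFF
    difference-of-Gaussians kernels, converted to spike waves by
    intensity-to-latency coding, and fed to an Integrate-and-Fire
    convolutional layer trained with unsupervised spike-timing-dependent
    plasticity (STDP). Per-voxel fMRI responses are modelled as a linear
    readout of one receptive-field location of the feature maps, selected
    by exhaustive cross-validated search. Fitted encoding models support
    image identification by predicted-response correlation, Bayesian image
    reconstruction from a prior image set under a multivariate Gaussian
    noise model, and Monte-Carlo noise-ceiling estimation from repeated
    presentations. Includes a synthetic stimulus/response generator so the
    full pipeline is testable without fMRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
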