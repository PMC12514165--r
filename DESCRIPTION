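Package: audenc
Title: Auditory Neural Encoding Models with Temporal Recurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and interprets encoding models of auditory neural responses.
    Stimulus cochleagrams (frequency-by-time spectrogram-like matrices) are
    mapped to per-neuron firing-rate time series by a family of causal
    encoders: linear spectro-temporal receptive field (STRF) models,
    linear-nonlinear (LN) models, network receptive field (NRF) and leaky
    dynamic network (DNet) models, 2-D convolutional networks, a
    windowed-attention Transformer, and stateful recurrent encoders built
    from a tonotopic locally connected layer feeding an Elman, GRU, LSTM or
    diagonal state-space core. Training follows the neural-response-fitting
    protocol (mean-squared error against the trial-averaged PSTH, AdamW
    updates, early stopping on validation loss), including truncated
    backpropagation through time with or without a gradient-free warmup.
    Model quality is scored with the raw and noise-corrected correlation
    coefficients based on the across-trial signal power. A gradient-ascent
    interpretation engine computes GradMaps, Dreams, latency energy traces,
    cross-model GradMap similarity matrices and dream-length activation
    curves for any fitted encoder. A synthetic stimulus-response simulator
    with known ground-truth STRFs, adaptation mechanisms and trial noise
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
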