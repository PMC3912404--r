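Package: rnnpb
Title: Two-Stream Recurrent Networks with Parametric Biases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements an Elman-style recurrent neural network with
    parametric bias (PB) units in which two recurrent hidden streams -- a
    fast "dorsal" (where) pathway and a slow "ventral" (what) pathway --
    are joined at the output layer by a horizontal product (element-wise
    multiplication of the two streams' linear output contributions).  The
    network supports three execution modes: learning (backpropagation
    through time with per-weight sign-based adaptive learning rates and
    adaptive per-sequence PB updates), recognition (frozen weights,
    windowed PB inference from an observed sequence), and prediction
    (closed-loop generation from a fixed PB vector).  A synthetic
    sensorimotor-trajectory generator produces the colour-channel-encoded
    cosine, square and circle curves used to train and evaluate the model,
    and a command-line driver reproduces the full training, recognition,
    prediction, generalization and speed-variant protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
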