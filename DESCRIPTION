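Package: quadnet
Title: Quadratic-Neuron Networks and EM Benchmarks for Gaussian Mixture
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feed-forward classification networks built from quadratic
    neurons, whose pre-activation is a product of two affine forms plus a
    weighted sum of squared inputs, trained by closed-form backpropagation
    with full-batch Adam.  Includes conventional (inner-product) networks
    under the same training loop, a Gaussian-mixture-model benchmark
    (stable posterior computation, Bayes-rule inference, expectation-
    maximization fitting, and pairwise-swap cluster label alignment), a
    synthetic Gaussian-mixture task generator with train/validation/test
    splitting, and experiment drivers that compare all methods on the same
    draws.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
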