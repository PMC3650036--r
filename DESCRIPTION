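Package: synitl
Title: Synergistic Information-Theoretic Learning for Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains small feedforward and fully recurrent neural networks by
    minimization of error entropy (MEE): steepest ascent on the Renyi
    quadratic information potential of the prediction errors, estimated by
    Gaussian-kernel (Parzen) density estimation. Optionally combines the
    synaptic MEE rule with a batch infomax intrinsic-plasticity rule that
    adapts each neuron's activation gain and bias to maximize the neuron's
    input-output mutual information. Includes a Mackey-Glass chaotic
    time-series generator, delay embedding and normalization utilities, and
    an experiment harness for paired with/without-intrinsic-plasticity
    comparisons, learning-rate and network-size sweeps, and kernel-density
    distribution diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
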