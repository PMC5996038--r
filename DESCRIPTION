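Package: facebias
Title: Shared, Idiosyncratic and Induced Face-Emotion Association Biases
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how facial identity biases emotion
    recognition. Simulates two-alternative anger/fear categorisation
    experiments with shared (observer-general), idiosyncratic
    (observer-specific) and experimentally induced face-emotion
    associations; decomposes post-test ratings or per-face decision biases
    into orthogonal shared and idiosyncratic components with a leave-one-out
    regression; fits a family of probit decision models in which
    associations shift the decision criterion or modulate perceptual
    sensitivity; compares models via cross-validated log-evidence with
    fixed-effects Bayes factors and random-effects exceedance
    probabilities; and analyses single-trial EEG encoding of decision
    covariates with cluster-based permutation statistics and jackknife
    latency tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
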