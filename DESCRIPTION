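Package: tigp
Title: Gaussian-Process Analysis of Transitive-Inference Learning Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing massed-training
    transitive-inference (serial learning) experiments. Generates the
    three-phase trial schedule in which the last two items of a seven-item
    list are massed before full training, simulates choice behaviour from
    associative (delta-rule with value transfer) and representational
    (noisy ordinal position) agents with log-normal reaction times, and
    analyses trial-level choice data with Gaussian-process regression:
    exact inference for log reaction times, Laplace-approximate inference
    with a binomial likelihood for choice accuracy, learning rates as the
    posterior derivative of the latent log-odds function, and a joint
    trial-by-symbolic-distance-by-joint-rank accuracy surface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
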