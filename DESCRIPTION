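Package: spikevision
Title: Orientation-Selective Spiking Neural Network for Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hierarchical spiking neural network for grayscale image
    classification built on the orientation selectivity of the early visual
    cortex. A motion-energy style bank of oriented derivative-of-Gaussian
    filters converts a static 28x28 image into V1 complex-cell firing rates
    (84 channels per pixel), which drive a layer of conductance-based
    Izhikevich neurons organised into orientation-preferring V2 pools with
    Gaussian orientation tuning and anti-preferred inhibition. V2 rates are
    converted to single-spike latency patterns and classified by a multiclass
    tempotron trained with the error-correcting P+/P- rule. Includes an IDX
    (MNIST-style) reader/writer, a seeded synthetic oriented-stroke digit
    generator, a preprocessing cache, parameter-sweep experiments and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    arrow,
    optparse
Config/testthat/edition: 3
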