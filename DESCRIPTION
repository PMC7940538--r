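Package: cercatag
Title: Bio-Inspired Cercal-System Escape-Response Model of the Cricket
    Terminal Abdominal Ganglion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical simulation of cricket cercal filiform-hair spiking
    under ambient air currents and simulated predator attacks, a leaky
    resistor-capacitor feature-map input layer, and a sparse bio-inspired
    neural network of the terminal abdominal ganglion (TAG) trained by
    backpropagation with a multi-objective loss.  Includes ablation variants
    of the TAG architecture, logistic-regression and multi-layer-perceptron
    comparators, magnitude pruning and L1-sparsified training, and an
    evaluation suite built around ROC curves, the tolerated false-positive
    rate at a fixed minimum sensitivity, and the Akaike information
    criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
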