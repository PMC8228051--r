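Package: vegdbn
Title: Deep Belief Networks for Mine Vegetation Cover Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Per-pixel identification of vegetation cover in open-pit mine
    imagery with a deep belief network: restricted Boltzmann machines trained
    by one-step contrastive divergence, stacked by greedy layer-wise
    pretraining, topped with a softmax classifier and fine-tuned by
    backpropagation. Includes a synthetic labeled-scene generator (green
    vegetation patches on yellowish-brown barren ground), HSV colour feature
    extraction, accuracy assessment (overall accuracy, confusion matrix,
    Cohen's kappa with rating bands, user/producer accuracy), and
    control-variable hyperparameter sweeps over network depth, hidden-layer
    width, learning rate, iterations and sample size.
License: MIT
Encoding: UTF-8
Imports:
    png,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
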