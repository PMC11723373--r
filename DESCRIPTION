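Package: seizcast
Title: Seizure Prediction and Detection from EEG Spectral Images with a
    Contractive Spike-and-Slab Convolutional Deep Belief Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for EEG-based epileptic seizure prediction and detection.
    Converts multichannel EEG recordings into band-power spectral images
    (theta, alpha, beta), trains a contractive spike-and-slab convolutional
    restricted Boltzmann machine (CssCRBM) with dual-variable probabilistic
    max-pooling by contrastive divergence, stacks trained layers into a deep
    belief network, and fine-tunes the stack with a self-attention head under
    a dual-task (classification plus Siamese verification) objective.
    Includes a synthetic EEG generator with class-dependent band-power
    signatures, exact-enumeration oracles for small models, evaluation
    metrics (sensitivity, false-positive rate per hour, accuracy, seizure
    prediction time), and stratified cross-validation helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
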