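Package: steatoq
Title: Hybrid Quantum-Classical Classification of Hepatic Steatosis Tiles
Version: 0.1.0
Authors@R: person("steatoq", "developers", role = c("aut", "cre"),
    email = "steatoq@example.org")
Description: Tools for grading hepatic steatosis in histology tiles and for
    deciding transplant suitability with a hybrid quantum-classical image
    classifier. Provides a dense statevector simulator for quantum
    depth-infused (data re-uploading) circuits with exact parameter-shift
    gradients, a small convolutional backbone trained with a false-negative
    penalizing weighted cross-entropy, a synthetic steatosis tile generator
    with pixel-exact fat-fraction ground truth, a federated averaging
    (FedAvg) simulation over disjoint balanced client shards, and evaluation
    utilities (lambda and training-set-size sweeps, slide heatmap
    reassembly) with a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    optparse,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
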