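Package: scglang
Title: Structure-Aware Coarse-Grained Protein Language Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a discrete, structure-aware coarse-grained language for
    proteins. Chains are segmented into secondary-structure fragments from
    classic DSSP output, each fragment is featurized as a 74-dimensional
    vector (amino-acid composition, PSSM/HMM evolutionary profiles, and
    DSSP-derived geometry), and a fixed-size token vocabulary is learned
    over fragment features with a vector-quantized autoencoder trained by
    minibatch gradient descent with a straight-through estimator. Proteins
    are then serialized into short token sentences. Includes alternative
    (random and length-shuffled) segmenters for ablation studies, a k-means
    vocabulary baseline, codebook-utilization diagnostics, and a synthetic
    data generator producing DSSP, PSSM and HHM fixtures so the whole
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    bio3d,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
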