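Package: spatchwork
Title: Multi-Slice Spatial Transcriptomics Integration with a Masked
    Variational Graph Autoencoder
Version: 0.1.0
Authors@R:
    person("Spatchwork", "Developers", email = "spatchwork@example.org",
           role = c("aut", "cre"))
Description: Integrates multiple spatial transcriptomics slices into a
    shared latent space, corrects batch effects across slices, and
    identifies spatial domains in 2D and 3D. The model is a masked
    variational graph autoencoder over per-slice k-nearest-neighbor
    spatial graphs joined block-diagonally, refined by deep embedded
    clustering (Student-t soft assignments against a sharpened target
    distribution) and by a mutual-nearest-neighbor triplet loss with
    readout aggregation of positive and negative neighborhoods.
    Includes a negative-binomial multi-slice simulator with known
    domains and controllable batch effects, model-based Gaussian
    mixture clustering of the latent embedding, clustering agreement
    metrics (ARI, NMI, AMI, V-measure) and local inverse Simpson's
    indices (iLISI, cLISI), expression denoising, marker ranking, and
    center-aligned 3D stacking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    rhdf5
Config/testthat/edition: 3
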