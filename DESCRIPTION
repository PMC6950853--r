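Package: molcycle
Title: CycleGAN Optimization of Molecules in a Reversible Latent Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Learns a pair of least-squares adversarial generators between two
    sets of molecules embedded in a reversible latent space, and uses the
    trained forward generator to optimize molecules under a structural
    similarity constraint. Provides SMARTS-based construction of the compound
    sets, penalized logP scoring (logP minus a synthetic-accessibility score),
    Morgan fingerprint Tanimoto similarity, latent optimization paths with
    best-under-threshold selection, iterative unconstrained optimization,
    evaluation metrics (success rate, non-identity, uniqueness, diversity), a
    random-forest activity oracle, and a fully synthetic grid-quantized latent
    backend so the whole workflow runs without external data or a pretrained
    autoencoder.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    pROC,
    randomForest,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
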