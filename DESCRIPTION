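Package: ncatrim
Title: Network Component Analysis with Iterative Edge Trimming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deconvolution of transcription-factor activities from gene
    expression data by Network Component Analysis (NCA), a bilinear
    decomposition E = AP constrained by a TF-gene connectivity pattern,
    extended with an iterative trimming algorithm that removes false
    TF-gene edges by per-gene forward stepwise regression scored with the
    small-sample corrected Akaike information criterion. Includes in-silico
    data augmentation to stabilise under-determined decompositions,
    genome-scramble permutation tests with median/MAD z-scores to call
    significantly perturbed transcription factors, and a synthetic-network
    benchmark generator (power-law in-degree topology, false-edge
    injection, noise, ROC and SNR scoring).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
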