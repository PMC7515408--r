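Package: arifuse
Title: No-Reference Quality Assessment of Fused Images via Arimoto Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Objective, no-reference quality assessment for image fusion.
    Implements the Arimoto-entropy fusion metric M_alpha, which scores a
    fused image by the generalized mutual information it shares with its
    two source images, together with four baseline metrics (Shannon mutual
    information, normalized mutual information, Tsallis divergence, and the
    Petrovic edge-preservation measure), six classical fusion algorithms
    (averaging, PCA, Laplacian and contrast pyramids, block-DCT, guided
    filtering) as test stimuli, and a deterministic generator of synthetic
    multi-focus and multi-modal (CT/MR-like) image pairs so the complete
    evaluation protocol runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
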