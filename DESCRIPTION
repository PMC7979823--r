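Package: melcpipe
Title: Single-Cell Analysis of Multiplexed Cyclic Immunofluorescence (MELC) Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end analysis of multi-epitope ligand cartography (MELC)
    acquisitions: registration of per-cycle fluorescence/bleach z-stacks to a
    phase-contrast reference, bleach-based background subtraction and
    illumination correction, extended-depth-of-field projection, rolling-ball
    normalization, random-forest pixel classification into nuclei/membrane/ECM
    probability maps, two-stage nucleus/cell segmentation, per-cell mean
    fluorescence quantification, threshold gating of immune cell types
    (including rare Lin-CD45+CD127+ innate lymphoid cells), 10 micrometer
    spatial niche and tissue-compartment analysis, and arcsinh/PCA/t-SNE
    phenotype clustering. Includes a synthetic MELC-run generator with full
    ground truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    randomForest,
    mgcv,
    Rtsne,
    cluster,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
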