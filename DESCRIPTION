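Package: endoscore
Title: Quantification of Endolysosomal Interactomes, Colocalization and
    Ratiometric pH Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipelines for endolysosomal cell biology:
    dual-epitope-tag IP-MS interactome enrichment scoring from spectral-count
    tables (abundance filtering, zero-count imputation, molecular-weight
    normalization, per-tag and combined fold changes, contaminant removal,
    over-representation testing), area-based puncta colocalization between
    fluorescence channels, ratiometric endolysosomal pH analysis of
    LAMP1-targeted green/red sensors (cell-body masking, bright-spot
    detection, per-punctum green-to-red ratios, puncta-count study weights,
    Welch and Mann-Whitney group comparisons), western-blot densitometry for
    V-ATPase assembly assays, and seeded synthetic-data generators providing
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
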