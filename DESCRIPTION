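Package: mitoscreen
Title: Simulation and Analysis of Time-Lapse RNAi Screens for Mitotic
    Phenotypes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to simulate and analyse high-content time-lapse RNAi
    screens for cell-division phenotypes. Provides a generative model of
    screening plates and nuclei movies (siRNA libraries, plate layouts,
    per-well cell event logs, rendered two-channel image stacks, ordinal
    manual scores), nuclei segmentation and per-object feature extraction,
    lineage tracking with mitosis detection by track splitting
    (MitosisCount), robust z-score plate normalization and rule-based hit
    calling for primary and validation screens, classification of
    post-knockdown cell fates (mitotic death, mitotic exit, cytokinesis
    failure, direct apoptosis), and scoring of RNA-pulldown proteomics
    (iBAQ quantification, target-versus-control enrichment, hypergeometric
    term enrichment).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: CellBasedAssays, Software, CellBiology, Visualization
RoxygenNote: 7.3.3
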