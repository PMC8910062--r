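Package: proxitome
Title: Comparative BioID Interactome Analysis with Functional Assay
    Quantification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of proximity-dependent biotinylation
    (BioID) interactomes: confidence scoring of prey-bait interactions
    against control runs with Bayesian false discovery rate gating and
    replicate-correlation quality control, bait-abundance normalization,
    classification of gained, lost, drug-restored, attenuated and
    non-responsive interactions, volcano statistics, over-representation
    testing, prey-profile localization inference by Jaccard distance
    against a compartment-marker compendium, and dot-plot and network
    exports. Also quantifies the accompanying functional assays:
    ratiometric surface-to-total measurements from 16-bit field images and
    membrane-potential (FLIPR) traces. Synthetic-data generators with
    known ground truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
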