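Package: spreadscreen
Title: High-Content Screening Pipeline for Cell Spreading and Adhesion Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete, scriptable analysis pipeline for microscopy-based
    high-content screens of cell spreading and adhesion on 96-well plates.
    Covers illumination correction and intensity rescaling, three-tier object
    segmentation (nuclei, whole cells by seeded propagation, cytoplasm by
    subtraction), neighbour analysis with a separated-cell filter,
    multi-parameter shape feature extraction, a capped boosted-stump phenotype
    classifier, percentage-of-control and virtual-row-shuffling B-score plate
    normalization, SSMD assay-quality scoring, rule-based hit selection and
    CSV/pivot export. A ground-truthed synthetic data generator stands in for
    the microscope and the compound library so that every stage can be
    exercised and validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
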