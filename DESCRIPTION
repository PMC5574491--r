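Package: cystscreen
Title: Phenotypic Analysis of 3D Cyst-Growth High-Content Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for plate-based 3D cyst-growth
    screens: segmentation and phenotypic quantification of two-channel
    (actin/nuclei) fluorescence z-stacks, plate normalization with
    replicate-adjusted Z'-factor quality control, cyst-size hit calling,
    Z'-gated PCA phenotypic profiling (restored / unchanged / novel
    phenotype classification), and Bliss-independence synergy analysis of
    two-compound dose grids. Includes a seed-controlled synthetic screen
    generator that renders cystic structures (bright actin ring, dim lumen,
    scattered nuclei) with exhaustive ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
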