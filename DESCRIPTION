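Package: dsstream
Title: Direction-Selectivity Analysis for Calcium Imaging and
    Intrinsic-Signal Retinotopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking retinal direction selectivity to
    visual cortical responses. Processes two-photon calcium imaging traces
    into baseline-normalized fluorescence (dF/F0) and trial-resolved
    response amplitudes; computes per-cell tuning statistics (direction
    and orientation selectivity indices, vector-sum preferred direction,
    temporal-frequency preference, ON-OFF index); compares neural
    populations between genotypes with PCA decomposition, grid
    segmentation, Yates-corrected chi-square classification, and
    normalized-difference indices; and segments retinotopically mapped
    visual areas from intrinsic-signal imaging stacks via Fourier phase
    maps, hemodynamic-delay subtraction, and visual-field sign maps.
    Includes a synthetic-data generator producing ground-truth-labeled
    recordings for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    signal,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
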