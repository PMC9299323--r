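Package: ctiq
Title: Automated CT Image Quality Metrics from Structure Coherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Fully automated, reference-free image quality evaluation for CT
    slices. A per-pixel structure coherence feature (SCF) -- windowed edginess
    normalized by the directional entropies of gradient and structure-tensor
    orientations -- partitions an organ mask into homogeneous and
    structure-edge regions, from which a noise level, a structure sharpness
    index (SSI) and, for co-registered reconstruction pairs, a structure
    alteration index (SAI) are computed without manual ROI placement. Also
    provides the manual-reference edge-slope measurement (perpendicular line
    profiles along a drawn edge polyline with 10-90% clipping), Pearson and
    Bland-Altman agreement statistics, a minimal DICOM CT slice reader and
    writer, and a synthetic contrast-enhanced liver phantom generator so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
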