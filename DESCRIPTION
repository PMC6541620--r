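Package: cellquant
Title: Quantitative Imaging and Motility Analytics for Cortically Enriched
    Proteins in Migrating Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell fluorescence quantification and cell-motility analytics
    for studies of cortical protein recruitment in migrating cells. Segments
    cells and nuclei from z-projected multi-channel stacks by adaptive
    thresholding, isolates a ~2 micrometre cortical ring, samples protrusion and
    seeded random boxes, and measures regional mean intensities, centrosome
    totals, nuclear-to-cytoplasmic ratios, aspect ratios, control-normalised
    folds and mask-based colocalization coefficients. Trajectory analytics cover
    average and hourly running speeds, time-averaged mean-squared displacement
    with linear-regression random-walk classification, and half-life fitting of
    drug-induced speed decay. Scratch-wound closure is quantified as residual
    area relative to time zero. A synthetic-data module generates cell-image
    phantoms, two-dimensional trajectories and wound series with known ground
    truth so every stage is testable end to end.
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
    minpack.lm,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
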