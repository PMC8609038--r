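Package: aggrescreen
Title: FRET Biosensor Screening Analysis for Seeded Protein Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for FRET-biosensor high-throughput screens of
    seeded alpha-synuclein aggregation. Gates per-cell flow-cytometry event
    tables, computes normalized FRET scores (percent FRET-positive times FRET
    MFI), standardizes compound scores to z-scores with all-concentration hit
    calling and Z'-factor assay quality control, quantifies microscopy readouts
    (pixelwise Pearson colocalization, puncta detection by Gaussian blur and
    white top-hat filtering, TFEB nuclear to cytosolic translocation ratios,
    galectin-3 puncta area fractions), and performs downstream proteomics
    set-overlap analysis (median normalization, log2 fold changes, altered-set
    overlap, replicate correlation, sample clustering). Ships seeded
    synthetic-data generators for flow plates, microscopy images and omics
    matrices so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    EBImage,
    jsonlite,
    yaml,
    tiff,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
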