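Package: txbodies
Title: Transcription-Body Imaging and Nascent-Transcript Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of micron-scale transcription bodies in
    early embryos: synthetic-data generation with ground truth (3D
    fluorescence stacks, timelapses, stranded paired-end read sets with
    planted nucleotide conversions), sub-voxel 3D spot localization by
    iterative Gaussian-mask fitting, transcription-body detection,
    identity/state classification and tracking over the cell cycle,
    per-nucleus enrichment statistics, DNA-FISH 3D distance analysis with
    Oligopaint probe validation, and a conversion-aware (SLAM-seq style)
    nascent-read classification stack with SNP consensus calling,
    fragment-level gene counting and chromosome-level hypergeometric
    enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
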