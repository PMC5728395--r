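Package: threecap
Title: Low-Input Capture-C Interaction Analysis and 3C Library Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for low-input Capture-C chromosome conformation
    capture experiments. Builds in-silico restriction-fragment maps of a
    reference genome, classifies aligned read slices into capture (viewpoint)
    and reporter fragments, removes PCR duplicates with a stringent
    wobble-tolerant coordinate-UMI filter, and constructs, pools, normalizes,
    windows and differentially compares per-fragment interaction profiles.
    Includes library-quality statistics (cis/trans composition, replicate
    correlation, qPCR-based digestion efficiency and mass quantification),
    probe design and count analysis for hybridization-based (NanoString-style)
    junction counting, and a synthetic 3C library simulator with ground truth
    so that every stage can be validated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomeInfoDb,
    GenomicAlignments,
    S4Vectors,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
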