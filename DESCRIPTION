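Package: phagemap
Title: Proximity-Labeling Interactomics for Nucleus-Forming Jumbo Phages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for mapping the protein interaction network of the
    jumbo-phage nuclear shell from proximity-labeling (miniTurboID) mass
    spectrometry. Implements host-peptide normalization of label-free peak
    areas, per-protein aggregation, normalized peak-area and fold-change
    enrichment scoring against a GFP-miniTurboID control, candidate selection
    with cross-bait overlap, evidence-typed interaction-network assembly and
    export, subcellular localization summaries, intron-aware spliced CDS
    extraction and translation for genome re-annotation, pairwise sequence
    identity statistics for homolog conservation, protein molecular-weight
    computation, and a seeded synthetic peptide-level experiment generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
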