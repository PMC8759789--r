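Package: nartscreen
Title: Deconvolution of DNA-Barcoded pMHC Multimer Screens for
    Neoantigen-Reactive T Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for quantifying neoantigen-reactive CD8+ T cells
    (NARTs) from DNA-barcoded peptide-MHC multimer screens. Covers
    neoepitope library selection from prediction tables, decoding of
    amplicon sequencing reads into clonally reduced (UMI-deduplicated)
    barcode counts, TMM-normalized negative-binomial enrichment testing
    against triplicate baseline samples, frequency estimation and
    relevance filtering of antigen-specific T-cell populations,
    longitudinal origin/engraftment/persistence classification across
    adoptive-cell-therapy time points, and cohort-level outcome
    statistics (Kaplan-Meier/log-rank, rank tests, proportion tests).
    Includes a synthetic-data generator that emulates every input class
    with exported ground truth, so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    Biostrings
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
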