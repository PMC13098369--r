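Package: pcgrn
Title: TF-Centered Hierarchical Gene Regulatory Network Inference via
    First-Order Partial Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a four-layer, transcription-factor-centered gene
    regulatory network from expression data using Pearson coexpression
    thresholds and first-order partial-correlation mediation tests,
    assembles the hierarchy by breadth-first layering from a known root
    TF, scores wet-lab verification tables (ChIP-PCR and RT-qPCR) into
    direct/indirect/unconfirmed percentages, and scans promoter
    fragments for the root TF's binding elements (GATA-box, TGGT-box,
    GGAT-box) with degenerate cores. Ships a synthetic linear-Gaussian
    cascade simulator that plants a known layered network, promoter
    elements and verification outcomes so every stage of the pipeline
    has a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
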