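Package: srnamap
Title: Organ-Specific Small RNA Regulatory Maps from Transcript, Small RNA
    and Degradome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds organ-specific small-RNA regulatory maps for non-model
    plant transcriptomes from three layers of sequencing evidence. Screens
    RPKM expression matrices for transcripts highly expressed in exactly one
    organ (fold, t-test and floor criteria), screens collapsed small-RNA
    libraries for organ-specific small RNAs, matches a mature miRNA reference
    against the libraries to build a renamed candidate catalog, screens
    candidate precursor transcripts by dot-bracket secondary structure
    (bracket coverage, stem-loop detection, miRNA/miRNA* duplex calls with
    2-nt 3' overhangs), detects phase-distributed miRNA-like RNAs on long
    stems, and validates miRNA-mediated cleavage with degradome 5'-tag
    evidence using three positional/abundance rules. Includes a synthetic
    data generator with planted ground truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
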