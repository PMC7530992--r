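Package: mztclear
Title: Maternal Transcript Clearance Analysis for the Maternal-to-Zygotic Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies maternal transcript decay during the human
    maternal-to-zygotic transition (MZT) from stage-wise FPKM expression
    matrices: fold-change threshold clustering of degradation patterns
    (Clusters I-IV, M-decay and Z-decay), zygotic-genome-activation (ZGA)
    dependence calling from transcription-inhibition (alpha-amanitin)
    counterfactuals, 3'-UTR CPE/PAS motif scanning and class comparison,
    single-embryo transcriptome concordance and decay-defect diagnosis in
    development-arrested embryos, and qPCR delta-Ct relative quantification.
    Ships a synthetic-data generator with planted ground truth so the full
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
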