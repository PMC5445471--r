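Package: quantdss
Title: Standard-Curve qPCR Quantification with a Quality-Control Decision
    Support System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Standard-curve based relative quantification of qPCR data with
    normalization to one or several reference genes and a hierarchical,
    user-tunable quality-control decision support system: nucleic-acid
    extraction control on reference genes, limit-of-detection and
    limit-of-quantification imputation of target copy numbers, and
    per-sample amplification-efficiency control from two sample dilutions.
    Includes platform-independent tab-delimited input with cross-gene
    consistency checking, auditable sample-by-gene result matrices with
    warnings, a classic delta-delta-Cq comparator, and a seedable
    synthetic-experiment generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
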