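Package: hccpm
Title: Phosphorylated Biomarker Prediction for Hepatocellular Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores candidate hepatocellular carcinoma (HCC) biomarkers from
    protein sequences and evidence annotations. Scans protein sequences for
    Prosite-syntax phosphorylation motifs with a sliding-window matcher and
    maps matched motifs to candidate kinases; scores kinase-substrate
    plausibility from tissue-expression evidence, shared GO cellular-component
    annotation, and cell-cycle co-expression; scores HCC-marker likelihood
    from pathway-level evidence; combines both into a phosphorylated-marker
    (HCCPM) classification and joins drug-target categories. Includes a
    seeded synthetic-corpus generator with a constructive ground-truth ledger
    so every scoring rule is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
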