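Package: pinsel
Title: Dysregulated Pathway Discovery via Pathway Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies dysregulated pathway sets that discriminate disease
    from control samples. Pathway activity is summarised per sample as the
    first principal component of the standardized member-gene expression
    submatrix; a weighted pathway interaction network is built from shared
    differentially expressed genes and highly co-expressed protein-protein
    interaction pairs, reduced to its top-weight edges, and a pathway set is
    grown greedily from a seed pathway to maximise repeated cross-validated
    SVM AUC. Includes a synthetic-data generator that emulates a two-group
    expression study with planted dysregulated pathways, overlapping pathway
    membership, and a scored protein interaction network, so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
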