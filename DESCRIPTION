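Package: miRsigAML
Title: MiRNA Expression Signatures for Pediatric AML Subtype Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for miRNA-expression-based classification of pediatric
    acute myeloid leukemia (AML) (cyto-)genetic subtypes. Implements
    median-Ct normalization of TaqMan-style arrays, a geometric-mean
    fold-change variance filter, unsupervised Ward/Pearson clustering with
    hypergeometric subtype-enrichment testing, one-vs-rest linear SVM
    signature discovery under double-loop (nested) cross-validation,
    cross-platform validation of signatures on an independent cohort
    restricted to overlapping miRNAs, and consensus miRNA-target calling
    across prediction databases with inverse-correlation screening.
    A synthetic-cohort generator with planted subtype signatures makes
    every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
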