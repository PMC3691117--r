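Package: panelcv
Title: Gene-Panel Class Prediction with Nested Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates small gene-expression biomarker panels for
    two-class diagnosis from microarray-style log2 expression data. Implements
    random-variance (moderated) t-test feature enrichment, support-vector-machine
    recursive feature elimination (SVM-RFE) down to a fixed panel size, a suite
    of classical expression classifiers (diagonal linear discriminant analysis,
    compound covariate predictor, nearest centroid, k-nearest neighbours, linear
    SVM), nested leave-one-out cross-validation with permutation significance of
    the error rate, technical-replicate concordance quality control, quantile
    normalization with median-polish probe-set summarization, and a synthetic
    cohort generator with planted differential transcripts for end-to-end
    testing of the whole workflow.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    limma,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
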