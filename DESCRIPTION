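Package: ffpesig
Title: Cross-Platform Translation of Gene-Expression Signature Scores
    from Fresh-Frozen to FFPE Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for adapting composite gene-expression signature
    scores (such as the 18-gene RAS pathway activation panel) from
    fresh-frozen (FF) microarray data to formalin-fixed
    paraffin-embedded (FFPE) material measured on count, FPKM and
    probe-level platforms. Implements housekeeping geometric-mean,
    per-sample median, and log2 z-score normalization; fold-change and
    missingness probe filtration with mean and max-mean-signal
    probe-to-gene collapse; per-sample composite signature scoring;
    principal-component sample-quality outlier flagging; pairwise
    Spearman concordance tables and a 2x2 Fisher exact test; a
    from-scratch nearest shrunken centroids classifier with fully
    nested leave-one-out cross-validation; and a generator for matched
    FF/FFPE multi-platform cohorts with planted RNA-degradation
    outliers and a two-class mutation structure, so the whole workflow
    can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
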