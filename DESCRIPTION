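Package: loscreen
Title: Screening for Large Offspring Syndrome in Bovine Pregnancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying large offspring syndrome (LOS) during
    bovine pregnancy. Implements the sex-specific 97th-percentile
    overgrowth classifier, a day-55 ultrasound six-measurement product
    index with control-derived screening threshold, exact binomial
    sex-ratio tests, maternal-leukocyte count-matrix analytics
    (median-of-ratios, TMM and upper-quartile normalization, average-linkage
    hierarchical clustering, a negative-binomial likelihood-ratio
    differential-expression engine with Cox-Reid dispersion estimation and
    dual-configuration consensus), reference-gene selection for qPCR, and
    comparative-CT (delta-delta-CT) quantification. Ships a seeded
    synthetic-cohort generator emulating the study design (twin embryo
    transfer, sex-biased fetal loss, overgrowth mixture, dam-correlated
    leukocyte transcriptomes) plus deterministic fixtures reconstructed
    from printed cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    DESeq2,
    ape,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
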