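Package: crossclock
Title: Cross-Species DNA Methylation Age Clocks and Aging EWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates elastic-net epigenetic clocks from
    methylation beta matrices, including dual-species clocks on the
    relative-age (age / maximum lifespan) and piecewise log-linear age
    scales, with leave-one-sample-out cross-validation. Provides an
    epigenome-wide association screen of age (per-probe Pearson
    correlation with Fisher z statistics), Stouffer meta-analysis across
    tissues, top-CpG selection and cross-tissue sector classification,
    CpG-island/TSS/chromatin-state enrichment statistics, sample-integrity
    QC (clustering purity, out-of-bag classification), and a synthetic
    multi-species methylation data generator with known age effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
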