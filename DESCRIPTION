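Package: teaAroma
Title: Seasonal Tea Aroma Profiling from GC-MS Peak Tables with
    Transcriptome and qPCR Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for comparing seasonal tea volatile
    profiles from integrated GC-MS peak tables: Kovats retention-index
    calibration against an n-alkane ladder, internal-standard absolute
    quantification, odor-activity-value (OAV) and terpene-index scoring,
    odor-dimension radar aggregation and group comparisons, together with
    desk-scale transcriptome statistics (FPKM, differential-expression
    calling, hypergeometric pathway enrichment) and 2^-ddCt qPCR relative
    expression. Ships a seeded synthetic-data generator with recorded
    ground truth so every stage is testable end to end without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
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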