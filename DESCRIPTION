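Package: ontodyn
Title: Developmental Time-Course Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for age-series (developmental) RNA-seq
    expression tables. Filters features on absolute and differential
    expression, summarises temporal expression (gene expression ranks,
    per-age and molecule-type profiles), clusters genes into temporal
    groups by exploratory factor analysis with Horn's parallel analysis
    and varimax rotation, computes set-association statistics
    (right-tailed Fisher/hypergeometric overlap, chi-square independence,
    activation z-scores, Benjamini-Hochberg adjustment), discovers
    upstream regulatory modules by iterative intraclass-correlation
    merging, and performs transcript-level analyses: variant-usage
    shifts, Durbin-Watson filtering of novel isoform candidates, and
    splice-event classification against reference transcript models.
    A synthetic-data module generates expression matrices, regulator
    networks and transcript structures with known ground truth so the
    whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
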