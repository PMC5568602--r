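Package: rgselect
Title: Reference Gene Discovery from RNA-seq Read Counts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate reference genes for qPCR normalization
    directly from RNA-seq read-count tables. Counts are normalized to reads
    per mapped million (RPMM), expression stability is ranked by the
    population coefficient of variation across conditions, and candidates
    are selected by sweeping dual thresholds (maximum CV, minimum reads per
    condition), optionally collapsed to ortholog level, and summarized as
    Venn region counts. Includes a proper-pair SAM counting stage, a
    synthetic count-table and alignment generator with planted invariant
    genes for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
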