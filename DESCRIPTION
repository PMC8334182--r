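Package: assayharvest
Title: Mining Rapid Drug-Residue Assay Datasheets from HTML and PDF Documents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end mining pipeline that turns semi-structured HTML and
    PDF documents describing commercial rapid drug-residue screening assays
    into a clean, reconciled master datasheet (drug, test, matrix, assay type,
    sensitivity, tolerance). Includes boundary-safe keyword-ensemble matching,
    header canonicalization against a field-alias dictionary, repair of the
    common structural table pathologies (banner headlines, embedded drug-class
    title rows, side-by-side repeated column groups, missing final rows),
    entity canonicalization via synonym tables with PMI-based synonym-candidate
    scoring, unit normalization to ppb, and upsert reconciliation of new
    records into a prior master sheet. Ships a seeded synthetic-corpus
    generator with ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    openssl,
    stats,
    tibble,
    tools,
    utils,
    xml2
Suggests: optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
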