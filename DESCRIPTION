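Package: bioscoop
Title: Biobank Sample Communication Format: Validation, Conversion and Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reference implementation of a biobank sample-communication
    format: a concrete donor+sample JSON record schema with validation
    against a shipped JSON Schema document, RFC 4180 CSV to JSON
    conversion, derived anthropometric indices (BMI, WHR, corpulence
    index), a deterministic mock-cohort generator, and an in-memory
    Lucene/Solr-style query engine (field, phrase and range terms with
    boolean operators) for sample search. Covers the full test workflow:
    data preparation, ingest and query.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
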