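Package: cypmatch
Title: Substrate Assessment of Drugs for Polymorphic CYP2 Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Normalizes raw medication-entry tables (German substance
    spellings, combination products, partial ATC coding), resolves drug
    names to canonical English names through an ATC-code-first cascade,
    classifies each drug's substrate status for polymorphic cytochrome
    P450 enzymes (CYP2D6, CYP2C9, CYP2C19) against substrate resources
    with explicit coverage semantics, and quantifies agreement between
    classification methods with Cohen's kappa, qualitative agreement
    bands, intersection summaries, and frequency-weighted disagreement
    reports. Ships a seeded synthetic-data generator emulating the
    structure of emergency-department adverse-drug-reaction medication
    lists so every stage is testable without licensed drug databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
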