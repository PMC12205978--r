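Package: bsnermap
Title: Language-Model-Assisted Curation of BioSample Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating heterogeneous BioSample key-value metadata.
    Extracts cell-line names and experimentally modulated genes from sample
    attributes with a pluggable text-generation backend (a deterministic
    scripted backend is provided for offline use), maps extracted names to
    Cellosaurus terms through a normalization ladder over names and scoped
    synonyms, resolves gene symbols against the HGNC multi-symbol table,
    disambiguates homonymous cell-line names via a structured selection
    prompt, audits attribute-name usage on a per-project basis, and scores
    predictions against a gold standard with four metrics: cell-line
    accuracy and coverage, and non-cell-line precision and recall.
    Includes a seeded synthetic fixture generator so the full pipeline is
    testable with no network access and no language model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    stringi,
    tibble,
    tools,
    utils,
    xml2
Suggests:
    httr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
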