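Package: mircurate
Title: Assisted Biocuration of miRNA-Disease Statements from the Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semiautomatic curation of microRNA-disease literature.
    Recognizes miRNA names with a nomenclature regular-expression grammar,
    annotates sentences against a multi-category term dictionary with automatic
    surface-variant generation, extracts candidate vocabulary by n-gram mining,
    filters annotated sentences with Boolean category expressions and typed
    conceptual structures (miRNA / effect / target gene / sample / disease),
    and exports structured curation snippets. Includes a synthetic gold-corpus
    generator so the whole pipeline is testable without external full texts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stringi,
    tibble,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
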