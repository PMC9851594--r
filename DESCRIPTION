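Package: smwbuilder
Title: Compile Tabular Schema Specifications into Semantic MediaWiki Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A command-line oriented toolchain for turning a tab-separated
    schema specification into a complete Semantic MediaWiki site definition
    (property pages, per-category templates and PageForms forms, category
    pages with Semantic Drilldown filter declarations, a main page) serialized
    as MediaWiki import XML, and for turning tabular data into importable wiki
    pages with progressive-number entity titles and one-to-many parent links.
    Companion facilities cover constraint-driven synthetic data generation,
    ASK-query construction with automatic (possibly inverse) property-chain
    resolution over the category graph, and export of subject-property-object
    facts in Prolog syntax including the relational decomposition of complex
    clinical properties into aspect facts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
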