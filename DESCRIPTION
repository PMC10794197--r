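Package: tadfminer
Title: Text Mining of Photophysical Properties of TADF Molecules from Marked-Up Articles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A literature-mining pipeline that turns marked-up scientific
    articles into a structured database of four molecular photophysical
    properties of thermally activated delayed fluorescence (TADF) emitters:
    maximum emission wavelength, photoluminescence quantum yield,
    singlet-triplet energy splitting, and delayed lifetime. Provides document
    ingestion for simplified publisher-style HTML/XML dialects, sentence
    segmentation and pluggable chemical named entity recognition, bracket- and
    equality-based abbreviation detection, property ontologies with
    auto-generated quantity grammars and standard-unit conversion, sentence and
    table parsers including special parsers for combined singlet/triplet
    energy columns, fractional quantum yields and shared lifetime cells, a
    corpus-frequency blocklist with document-scoped forward-looking compound
    resolution (the ThemeCompound model), physical-range and unit cleaning,
    SMILES-based structure filters, database serialization to CSV and JSON,
    precision/recall/F-score evaluation with accumulative convergence curves,
    and a synthetic-corpus generator with gold-standard annotations so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    yaml,
    stringr,
    withr,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
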