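Package: phenoxp
Title: Logical Definitions for Phenotype Ontologies via Entity-Quality Cross-Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for logically defining pre-composed phenotype classes as
    entity-quality (EQ) class intersections. Reads and writes the OBO flat-file
    dialect used by cross-product (XP) definition files, converts EQ
    descriptions (entity, quality, optional second entity, modifier, entity
    whole) to and from genus-differentia intersections and OWL Manchester text,
    decomposes phenotype class labels into candidate EQ definitions with an
    Obol-style grammar, computes deductive closure over merged ontologies with
    a forward-chaining rule reasoner, and validates definition sets by
    recapitulating and proposing is_a links, with curation reports, consistency
    lints and coverage statistics. Includes hand-built mini-ontologies for the
    classic worked examples and a seeded generator of random ontology suites
    whose entailments are known by construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
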