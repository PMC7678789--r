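Package: phenochar
Title: Ontology-Aware Recording of Continuous Phenotype Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless store and toolkit for recording continuous
    phenotype characters (e.g. "length of perigynium beak") against a
    home-grown anatomy/quality ontology. Characters must be named with a
    controlled of/between grammar and defined by anatomical landmarks
    (from/to/include/exclude/at) before any measurement can be recorded;
    landmark terms unknown to the ontology are registered with verbal
    definitions and receive permanent identifiers. Existing characters
    can be searched, reused (incrementing usage counts) or cloned and
    enhanced with shared creatorship and an OWL-style equivalence link.
    Includes a measurement table with CSV import/export, one-way OBO and
    Turtle ontology export, seeded fixture generators emulating a
    Carex-like ontology, and evaluation metrics for definition
    convergence, Likert survey scoring, weighted influence strength and
    error-rate accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
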