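Package: muscleLogic
Title: Anatomy Ontology Reasoning and Ontology-Expanded Literature Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in-memory model for anatomy ontologies with logically defined
    muscle classes (attachments, innervation, developmental origin), a
    polynomial-time EL-fragment reasoner based on completion-rule saturation,
    a Protege-style DL query engine, a pre-reasoned transitive-closure
    exporter for reasoner-free databases, and a Textpresso-style semantic
    search over plain-text corpora that expands queries through the ontology
    so that synonym and subclass mentions are retrieved where keyword search
    fails. Ships a programmatically built fixture ontology of the mammalian
    feeding muscles together with a synthetic-corpus generator used to
    benchmark keyword versus semantic retrieval.
License: MIT + file LICENSE
Encoding: UTF-8
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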