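Package: stageont
Title: Stage-Indexed Developmental Anatomy Ontologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and maintaining stage-indexed anatomy
    ontologies in the style of the mouse developmental anatomy resources:
    an abstract (stage-independent) ontology whose terms carry first/last
    developmental-stage annotations and typed DAG edges (part-of, is-a,
    develops-from), algorithms to instantiate per-stage timed ontologies
    and to derive the abstract ontology back as the union of timed graphs,
    a persistent timed-to-abstract identifier mapping, compound-name
    disambiguation with print names, structural validation and version
    diffing, OBO-format input/output, and a deterministic synthetic
    fixture generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'core-model.R'
    'obo-io.R'
    'staging.R'
    'naming.R'
    'validate.R'
    'fixtures.R'
    'cli.R'
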