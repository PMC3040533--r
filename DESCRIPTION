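Package: sadishare
Title: Semantic Annotation Services, Workflow Planning and Query Resolution
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained implementation of the SADI semantic-web-service
    contract and a SHARE-style query engine. SPARQL SELECT queries and OWL-DL
    class definitions are decomposed into requirements, matched against a
    registry of typed annotation services, concretized into an executable
    workflow, and resolved over a transient materialized RDF graph. Includes a
    minimal RDF data model with Turtle and RDF/XML serialization, a
    forward-chaining instance classifier for a positive-existential OWL
    fragment, a clinical worked example (trend classification of blood
    creatinine time courses via linear regression), and a synthetic patient
    cohort generator with emitted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, xml2, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'namespaces.R'
    'AllClasses.R'
    'AllGenerics.R'
    'graph.R'
    'turtle.R'
    'rdfxml.R'
    'io.R'
    'sparql.R'
    'class-expression.R'
    'ontology.R'
    'reasoner.R'
    'service.R'
    'registry.R'
    'planner.R'
    'engine.R'
    'ols.R'
    'demo-domain.R'
    'cohort.R'
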