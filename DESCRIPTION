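Package: ontoreg
Title: Ontology-Driven Clinical Data Registries with Hybrid Relational Storage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An engine for clinical data registries in which both the data
    model and the user interface of a registry are declared in an OWL ontology
    conforming to a built-in metamodel.  Ontologies are persisted in a hybrid
    relational schema (one table per ontology-language metaclass plus typed
    value tables, in the style of entity-attribute-value clinical stores) kept
    in sync with a statements table that acts as the universal interface.
    Class and property hierarchies are indexed with a nested-set labeling so
    transitive subsumption queries become interval tests.  Application
    ontologies are validated against the metamodel, compiled into renderable
    form models, and operated through a constraint-enforcing instance API with
    soft delete and dependent-cascade semantics.  Data are extracted as XML
    documents or as a relational SQL mirror, and a bulk load path feeds the
    statements table directly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'vocab.R'
    'statements.R'
    'classify.R'
    'owl-io.R'
    'gtab.R'
    'hierarchy.R'
    'metamodel.R'
    'repository.R'
    'propagate.R'
    'structural.R'
    'queries.R'
    'ontology-io.R'
    'forms.R'
    'instances.R'
    'extract.R'
    'fixtures.R'
    'cli.R'
    'ontoreg-package.R'
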