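# ontoreg

Ontology-driven clinical data registries with hybrid relational storage.

## What it is

Research groups run registries — case report forms collecting
demographics, clinical manifestations, laboratory results, treatments —
whose data model changes for the life of the study. `ontoreg` is an engine
in which **both the data model and the user interface of a registry are
declared in an OWL ontology** conforming to a built-in metamodel. Nothing
is programmed per project: the engine interprets the ontology, so changing
the registry means editing statements, not migrating schemas.

Under the hood:

* **Hybrid relational storage.** A statements table holds every triple and
  serves as the universal interface; one table per ontology-language
  metaclass role (resource, class, property, domain, range, …) plus one
  typed value table per datatype (the entity–attribute–value pattern of
  clinical stores, organized along OWL) are kept in sync with it by
  transactional propagation. Resources get short integer identities;
  nothing is ever physically deleted, only flagged.
* **Nested-set hierarchy index.** Each node of the class (and property)
  hierarchy is labeled with a `(left, right)` interval, so transitive
  subsumption and instance queries are interval tests, not recursion.
  Multiple inheritance is handled by duplicating the node (with its
  subtree) under each parent; the index is batch-built once after a bulk
  load — taxonomies of ~16,000 classes build in seconds.
* **Metamodel + validator.** Forms are classes instantiating the
  `DataStructure` metaclass; fields are properties punned as instances of
  one of eleven `FormElement` widget subclasses with layout/behavior
  facets (`webRow`, `webColumn`, mandatory, id, description, edition lock,
  directly-dependent); option lists are `AllowedValues`/`CodedValues`
  subclasses with ranked, optionally coded options. Eleven coded rules
  (`r1`–`r11`) validate an application before it compiles.
* **Constraint-enforcing CRUD.** Creation and update run a fixed-order
  gate (mandatory → id uniqueness → options → types); deletion soft-flags
  and cascades over directly-dependent links; creations on `Reportable`
  forms emit exactly one notification each.
* **Extraction.** Per-specification XML exports (recursive or referencing),
  a relational SQL mirror ("tables become classes, columns become
  properties"), and a bulk `ontoload()` path that feeds the statements
  table directly and provably reaches the same state as statement-wise
  upload.

## Worked example

```r
library(ontoreg)

repo <- init_repository()                    # in-memory; metamodel pre-loaded
app  <- generate_registry(registry_params(seed = 1))
app
#> <statement_set> 966 statements; ontology <http://ontoreg.org/fixtures/registry1>; imports: 1

upload_ontology(repo, app)
repo
#> <ontoreg_repo> 1027 statements (1027 live), 266 resources

validate_application(app)
#> <validation_report> VALID: 0 errors, 1 warnings
```

The 966-statement fixture is a registry in the shape of the engine's
motivating use case (a case root plus sections such as
`Precipitating_Factors`, `Previous_Manifestations`, `Laboratory`,
`Treatment`); the one warning is its deliberately included `SubForm`
field, a declared-but-unsupported widget. Compile and populate it:

```r
model <- compile_forms(app)
model
#> <form_model> application <http://ontoreg.org/fixtures/registry1#Registry>: 8 forms, 7 menu entries
head(model$menu$label, 3)
#> [1] "Cardiac Involvement" "Clinical Manifestations" "Laboratory"

ns  <- ss_ontology_iri(app)
pop <- populate_instances(repo, ns, registry_params(seed = 1, n_cases = 12))
head(list_instances(repo, model$case_root)[, 1:3], 3)
#>   instance_id                                            instance     f_case_1
#> 1         267 http://ontoreg.org/fixtures/registry1/data#Case_267 CASE-1-00001
#> 2         276 http://ontoreg.org/fixtures/registry1/data#Case_276 CASE-1-00002
#> 3         286 http://ontoreg.org/fixtures/registry1/data#Case_286 CASE-1-00003
length(notifications(repo))
#> [1] 26                     # one per creation on a Reportable form
```

The description column (`f_case_1`, the id field) is what a case list
displays. Deleting a case cascades over directly-dependent records only:

```r
length(delete_instance(repo, pop$cases[1]))
#> [1] 8                      # the case + its dependent child records, flagged
export_sql(repo, ns)
#> <relational_script> 8 tables, 92 rows
cat(substr(run_extractions(repo, ns)[[1]], 1, 200))
#> <?xml version="1.0" encoding="UTF-8"?>
#> <extraction class="http://ontoreg.org/fixtures/registry1#Case" recursive="true">
#>   <record id="276" class="Case">
#>     <field name="f_case_1">CASE-1-00002</field>
```

The SQL script executes on any empty SQL-92 database (row counts equal
live instance counts per form); the recursive XML export inlines each
case's laboratory and section records as nested elements.

## Layout

* `R/` — implementation (statement model and OWL I/O, repository and
  propagation, nested-set index, metamodel and validator, form compiler,
  instance CRUD, extraction, generators, CLI).
* `inst/schema/` — the repository DDL (portable SQL-92), the form-model
  JSON schema, and the XML-export XSD.
* `vignettes/ontology-driven-registries.Rmd` — the methods vignette: the
  storage and indexing model, the metamodel semantics, design decisions
  and limitations.
* `tests/testthat/` — unit, property and acceptance suites.
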