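---
title: "Ontology-driven clinical registries: model, storage and constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-driven clinical registries: model, storage and constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoreg)
```

## The problem

Clinical research groups collect structured data — case report forms with
demographics, manifestations, laboratory results, treatments — and the data
model changes continuously as the study evolves.  Conventional database
applications make every model change a schema migration plus a programming
task.  `ontoreg` takes the declarative route: **both the data model and the
form layout of a registry are stated in an OWL ontology** conforming to a
small built-in metamodel, and the engine interprets that ontology directly.
Adding a variable to a running registry means adding statements, never
altering tables or code.

## The storage model

Ontologies resemble databases operationally but need a persistence layer.
`ontoreg` uses a *hybrid* relational scheme, between the two classical
extremes:

* *schema-oblivious* — one big statements (triple) table: flexible, but
  every query becomes graph traversal;
* *schema-aware* — one table per class: fast, but every model change is a
  DDL change.

The hybrid keeps **one table per ontology-language metaclass role**
(resource, class, property, domain, range, subsumption edge, instance-of)
plus **one value table per datatype** (string, integer, float, boolean,
date, datetime) and one for resource-valued properties — the
entity–attribute–value pattern that EAV clinical stores have long used,
organized along the ontology language rather than the application.
Resources are identified by short monotone integer ids rather than their
IRIs (an identity-based scheme: joins on integers, not long strings).

A single **statements table** stores every asserted triple and acts as the
universal interface: asserting or retracting a statement there propagates
into all structural tables transactionally.  The design contract is
checkable and checked: at any point, rebuilding the structural tables from
scratch from the live statements must reproduce the incrementally
maintained state exactly (`rebuild_structural()` versus
`structural_state()`).  The classical mechanism for this propagation is a
set of database triggers; here it is application-level code inside the
transaction boundary, with the same observable semantics — the conformance
suite asserts the statements-table-as-interface behavior, not the
mechanism.

One propagation rule deserves a note: a literal value is hosted in the
value table of its **property's declared range** (not of the literal's own
datatype tag), defaulting to the string table with a warning when no range
is declared.  Because statements may arrive in any order, a range
declaration arriving *after* values re-places the existing live rows
(`migrate_values()`); this keeps propagation order-independent, which the
rebuild-equality contract requires.

Nothing is ever physically deleted.  Every table carries a delete flag;
retraction, instance deletion and ontology replacement all flag rows.  The
invariant "total physical row count never decreases" is asserted across the
whole random-mutation suite.  The editorial alternative to deleting a class
or property from a running project is `deprecate()`: deprecated fields
render read-only and are exempt from mandatory checks; deprecated forms
refuse new instances (reads remain allowed — the engine never blocks access
to collected data).

### The nested-set hierarchy index

Transitive queries — all subclasses of *digestive disease*, all instances
of a class including its descendants — are a recursion problem in plain
SQL.  The class and property hierarchies are therefore indexed with the
**nested-set model**: a depth-first pass labels every node with a
`(left, right)` interval such that descendants are exactly the nodes whose
labels fall strictly inside the interval.  Queries become interval
comparisons; no recursion is ever executed at query time.

Choices the encoding forces or leaves open:

* children are visited in **ascending resource-id order**, so identical
  edge sets always produce identical labelings (reproducibility);
* labels are 1-based consecutive integers; a pure tree of *N* placements
  uses exactly `1..2N` (asserted as an invariant);
* **multiple inheritance** is handled by duplicating the node under each
  parent — and, necessarily, duplicating its whole subtree recursively,
  because a placement's interval must contain all of its descendants'
  intervals.  Queries collapse duplicates back to canonical resources.
  This trades storage (placement count can exceed resource count) for
  constant-shape queries; with the multiparent fractions typical of
  registry taxonomies (~5–10%) the overhead is small.
* duplication is why incremental maintenance is costly: inserting one class
  shifts labels globally.  Early engine designs that relabeled on every
  class insert do not scale to taxonomies with tens of thousands of
  classes, so the index is **batch-built once after a bulk load**
  (`insert_resource()` also offers `relabel_incremental` for single
  insertions, and `mark_stale` which defers to the next batch build;
  queries on a stale index are refused).  A 15,982-class taxonomy — the
  scale of the largest deployed project the engine targets — batch-builds
  in seconds.

## The metamodel

Applications conform to a fixed vocabulary (namespace
`r mm_ns()`):

* an **Application** instance names the registry; forms are classes
  instantiating the **DataStructure** metaclass (a *metaclass*: its
  instances are themselves classes) and subclassing **ApplicationItem**;
* form fields are properties *punned* as instances of one of the eleven
  **FormElement** subclasses — Checkbox, Combobox, Graphic,
  HyperlinkProperty, ImageProperty, LiteralProperty,
  MultilineStringProperty, RadioButton, SingleCell, Password, SubForm
  (SubForm accepted but unsupported: the validator warns, the compiler
  skips it);
* seven facets control layout and behavior: `webRow`/`webColumn` (1-based
  grid position; their base is our choice, the grid is the metamodel's),
  `webDescriptionProperty` (shown in headers and lists),
  `webMandatoryProperty`, `webIdProperty` (unique identifier — id implies
  mandatory), `webEditionDisabled`, and `webDirectlyDependent` (values
  that cannot exist without their owner; drives the delete cascade);
* constrained fields range over a subclass of **AllowedValues** whose
  instances are the options; AllowedValues is a subclass of
  **OrderedItem**, so options carry an integer rank (`order`; ties broken
  by IRI — the rank property is our naming, the ordering capability is the
  metamodel's).  A **CodedValues** subclass additionally attaches a string
  `code` to each option, the usual pattern for binding forms to coding
  systems;
* menu entries are object properties typed **MenuItem**, linking the case
  root to the other forms — simultaneously data links and navigation;
* forms subclassing **Reportable** emit a creation notification (the
  delivery channel — e-mail in a portal deployment — is a pluggable hook
  here, `set_notify_hook()`);
* **DataExtraction** instances declare what to export and whether object
  properties are traversed recursively.

`validate_application()` enforces conformance as eleven coded rules
(`r1`–`r11`), each designed to be independently triggerable — the test
suite carries one single-mutation fixture per rule and asserts that it
fires exactly that rule.  Missing grid positions are reported under a
separate `layout` code: the metamodel text treats row/column as
descriptive, but a compiler cannot place an unpositioned field, so we fail
loudly on layout and stay permissive on flags (missing booleans default to
false).

Access-control vocabulary (roles, authorizations) is parsed if present but
never enforced; it is outside this engine's scope.

## Forms and the constraint gate

`compile_forms()` turns a valid application into a deterministic,
JSON-renderable form model (schema shipped under `inst/schema/`) — the
engine's stand-in for a live web portal: everything a renderer needs is in
the bundle, built dynamically from the ontology.  The case root is
identified structurally as the one DataStructure no menu entry points to.

Instance CRUD runs every mutation through a fixed-order constraint gate:
**mandatory → id uniqueness → option membership → value types**.  The
order is a design choice (the metamodel implies the checks, not their
order); fixing it makes rejection codes deterministic and testable.  A
rejected mutation writes nothing.  Deletion flags the instance and
cascades over `webDirectlyDependent` links, computed as transitive
reachability up front and verified in the suite against an independent
graph-reachability oracle.  Passwords are stored as opaque strings and
never exported; Graphic/Hyperlink/Image values are stored as string
references, never binary payloads.

Instance data live under a derived namespace (`<application IRI>/data`),
separate from the model namespace.  Replacing the model ontology therefore
cannot silently destroy collected data: a replacement that drops a class
whose instances are still live is refused and rolled back.

## Extraction

* `run_extractions()` produces one XML document per DataExtraction
  instance (XSD shipped).  `recursive = TRUE` inlines referenced objects
  as nested records, expanding each instance at most once per document
  (cycles degrade to references); `recursive = FALSE` emits `ref`
  attributes.  Coded options are exported as label text plus a `code`
  attribute — both, because consumers differ on which they want.
* `export_sql()` mirrors the application relationally — tables become
  classes, columns become properties: one table per DataStructure, typed
  columns from property ranges, foreign keys for single-valued object
  properties and link tables for multi-valued ones (cardinality is decided
  from the live data, the ontology not declaring it).  Identifiers are
  mangled deterministically (lower-case, non-alphanumerics to `_`) and
  double-quoted, and collisions are an error.  The suite executes every
  generated script on an empty SQLite database through Python's stdlib —
  an executor independent of this package — and compares row counts.
* `ontoload()` is the bulk ingestion path: statements are fed into the
  statements table directly with propagation deferred, then one structural
  rebuild and one hierarchy batch build run at the end.  Its end state is
  asserted identical to the statement-by-statement upload path.

## The synthetic-data generators

No deployed registry content is published, so the package generates its
own study conditions (`generate_registry()`, `populate_instances()`,
`generate_hierarchy()`, `generate_registry_dump()`), seed-deterministic
throughout:

* registry defaults emulate the deployed envelope: a few hundred cases
  (default 300, projects range to 2000) and 60–600 variables per case
  (default 8 forms × 6–12 fields), with clinically named sections
  (precipitating factors, previous manifestations, laboratory,
  treatment...), every widget kind and facet exercised, option lists on
  ~30% of fields, and configurable Reportable / directly-dependent
  fractions;
* value distributions are uniform over options, bounded uniform numbers
  and ISO dates in a fixed window — *structural* realism only.  Passing
  tests certify the engine's mechanics (propagation, indexing, constraint
  enforcement, extraction counting) on data of realistic shape and scale;
  they say nothing about clinically realistic value distributions,
  missingness patterns or inter-field correlations, which real registries
  have and these fixtures do not;
* the hierarchy generator grows a rooted forest under a depth cap and then
  gives a fraction of nodes a second, lower-numbered parent (acyclic by
  construction); its stress preset matches the largest deployed taxonomy
  (15,982 classes);
* the dump generator emits a model plus population as raw statements
  (~10^5 statements at defaults), the shape of a full registry dump, to
  exercise the bulk path at deployed-project magnitude.

## Numerical and procedural choices

* Supported literal datatypes are a closed practical set
  (string/integer/float/boolean/date/datetime); anything else is rejected
  at parse time rather than silently coerced.
* Serialization is canonical: statements sorted by (subject, predicate,
  object), blank nodes relabeled `_:b1...` in canonical order, so equal
  statement sets serialize byte-identically; equality of ontologies is
  multiset equality modulo blank relabeling (`ss_equal()`).
* Blank nodes are skolemized into the owning namespace before storage
  (the store is identity-based) and restored on download.
* Statements are globally deduplicated across namespaces; a triple is
  owned by the first namespace asserting it.
* `upload_ontology(mode = "replace")` synchronizes a namespace as a
  verified delta (retract-what-vanished, assert-what-is-new) inside a
  transaction — observably equal to soft-delete-all-then-assert, with far
  less row churn; `mode = "incremental"` merges additions only.
* Retraction guards are symmetric: retracting the class typing of a class
  with live instances is refused, and — by extension of the same
  principle, the source design documenting only the class case — so is
  retracting the property typing of a property with live values.

## Problem sizes in the verification suite

The acceptance suite and `scripts/acceptance.R` run the properties at the
sizes the package treats as its study conditions: 50 fixture ontologies for
round-trip fidelity; 200 random assert/retract sequences (up to 500
operations each) against the from-scratch rebuild; 1,000 random hierarchies
(5–2,000 resources) against the recursive-closure oracle plus the
15,982-class batch build; 20 fixtures for bulk/statement-wise load
equivalence plus a ~10^5-statement ingest; 1,000 accepted CRUD mutations
followed by an independent whole-repository audit; 100 random dependency
trees for cascade reachability; and exact count reconciliation between the
repository, the SQL mirror (executed in SQLite) and the XML exports.

## Known limitations

* No reasoning, SPARQL or SWRL: only asserted statements are stored and
  queried; no OWL species checking is performed.
* Single-writer: transactions protect each API call, not concurrent
  writers.
* The nested-set duplication strategy is exponential on pathological DAGs
  (dense multiple inheritance); registry taxonomies are nowhere near that
  regime.
* `equivalentClass` merging, access control and scheduled (e.g. daily)
  extraction runs are out of scope; the host system owns scheduling.
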