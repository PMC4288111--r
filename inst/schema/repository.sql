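-- ontoreg repository schema, version 1.
-- Portable SQL-92 DDL documenting the hybrid storage contract: one
-- statements table as the universal interface, one table per
-- ontology-language metaclass role, one value table per supported datatype
-- plus one for resource-valued properties, and the nested-set hierarchy
-- index.  The reference implementation keeps these tables in an embedded
-- in-process store persisted as one delimited text file per table; any SQL
-- backend hosting this DDL satisfies the same contract.
-- Nothing is ever physically deleted: every table carries a soft-delete
-- flag ("deleted"), and resource ids are monotone and never reused.

CREATE TABLE statements (
  id            INTEGER PRIMARY KEY,     -- monotone, append-only
  subject_id    INTEGER NOT NULL,        -- -> resources.id
  predicate_id  INTEGER NOT NULL,        -- -> resources.id
  object_id     INTEGER,                 -- -> resources.id (resource objects)
  object_lex    VARCHAR(4000),           -- lexical form (literal objects)
  obj_kind      VARCHAR(10) NOT NULL,    -- 'resource' | 'literal'
  lit_type      VARCHAR(10),             -- string|integer|float|boolean|date|datetime
  ontology_ns   VARCHAR(1000) NOT NULL,  -- owning ontology namespace
  deleted       INTEGER NOT NULL         -- soft-delete flag
);

CREATE TABLE resources (
  id            INTEGER PRIMARY KEY,     -- identity-based short id
  iri           VARCHAR(1000) NOT NULL,  -- unique per repository
  kind          VARCHAR(20) NOT NULL,    -- named_class|metaclass|datatype_property|
                                         -- object_property|annotation_property|
                                         -- individual|ontology|datatype
  ontology_ns   VARCHAR(1000) NOT NULL,
  deprecated    INTEGER NOT NULL,
  deleted       INTEGER NOT NULL
);

CREATE TABLE classes    (resource_id INTEGER NOT NULL, deleted INTEGER NOT NULL);
CREATE TABLE properties (resource_id INTEGER NOT NULL, deleted INTEGER NOT NULL);

CREATE TABLE domains (
  property_id INTEGER NOT NULL, class_id INTEGER NOT NULL,
  stmt_id INTEGER, deleted INTEGER NOT NULL
);
CREATE TABLE ranges (
  property_id INTEGER NOT NULL, range_id INTEGER NOT NULL,
  stmt_id INTEGER, deleted INTEGER NOT NULL
);

CREATE TABLE subclass_edges (
  child_id INTEGER NOT NULL, parent_id INTEGER NOT NULL,
  stmt_id INTEGER, deleted INTEGER NOT NULL
);
CREATE TABLE subprop_edges (
  child_id INTEGER NOT NULL, parent_id INTEGER NOT NULL,
  stmt_id INTEGER, deleted INTEGER NOT NULL
);

CREATE TABLE instance_of (
  instance_id INTEGER NOT NULL, class_id INTEGER NOT NULL,
  stmt_id INTEGER, deleted INTEGER NOT NULL
);

CREATE TABLE imports_t (
  importer_iri VARCHAR(1000) NOT NULL, imported_iri VARCHAR(1000) NOT NULL,
  stmt_id INTEGER, deleted INTEGER NOT NULL
);

-- one value table per supported datatype; the hosting table always matches
-- the property's declared range (undeclared ranges default to string)
CREATE TABLE value_string   (instance_id INTEGER NOT NULL, property_id INTEGER NOT NULL, lex VARCHAR(4000), stmt_id INTEGER, deleted INTEGER NOT NULL);
CREATE TABLE value_integer  (instance_id INTEGER NOT NULL, property_id INTEGER NOT NULL, lex VARCHAR(40),   stmt_id INTEGER, deleted INTEGER NOT NULL);
CREATE TABLE value_float    (instance_id INTEGER NOT NULL, property_id INTEGER NOT NULL, lex VARCHAR(40),   stmt_id INTEGER, deleted INTEGER NOT NULL);
CREATE TABLE value_boolean  (instance_id INTEGER NOT NULL, property_id INTEGER NOT NULL, lex VARCHAR(5),    stmt_id INTEGER, deleted INTEGER NOT NULL);
CREATE TABLE value_date     (instance_id INTEGER NOT NULL, property_id INTEGER NOT NULL, lex VARCHAR(10),   stmt_id INTEGER, deleted INTEGER NOT NULL);
CREATE TABLE value_datetime (instance_id INTEGER NOT NULL, property_id INTEGER NOT NULL, lex VARCHAR(25),   stmt_id INTEGER, deleted INTEGER NOT NULL);
CREATE TABLE value_resource (instance_id INTEGER NOT NULL, property_id INTEGER NOT NULL, object_id INTEGER, stmt_id INTEGER, deleted INTEGER NOT NULL);

-- nested-set hierarchy index: each placement labeled with a (left, right)
-- interval; multi-parent resources are duplicated (one placement per
-- parent, subtrees copied recursively)
CREATE TABLE hierarchy_index (
  node_id     INTEGER NOT NULL,
  resource_id INTEGER NOT NULL,
  lft         INTEGER NOT NULL,
  rgt         INTEGER NOT NULL,
  kind        VARCHAR(10) NOT NULL      -- 'class' | 'property'
);
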