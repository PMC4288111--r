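# Independent oracles and small fixture builders used across the suite.

# Recursive transitive closure over a child->parent edge set (the oracle the
# nested-set index is checked against; plain depth-first search, no interval
# logic).
closure_oracle <- function(edges) {
  kids <- split(edges$child, edges$parent)
  desc <- function(r) {
    out <- integer(0); frontier <- r
    while (length(frontier)) {
      nxt <- unique(unlist(kids[as.character(frontier)], use.names = FALSE))
      nxt <- nxt[!is.na(nxt)]
      frontier <- setdiff(nxt, out)
      out <- union(out, frontier)
    }
    sort(out)
  }
  pars <- split(edges$parent, edges$child)
  anc <- function(r) {
    out <- integer(0); frontier <- r
    while (length(frontier)) {
      nxt <- unique(unlist(pars[as.character(frontier)], use.names = FALSE))
      nxt <- nxt[!is.na(nxt)]
      frontier <- setdiff(nxt, out)
      out <- union(out, frontier)
    }
    sort(out)
  }
  list(descendants = desc, ancestors = anc)
}

# Execute a SQL script in an empty SQLite database through Python's stdlib
# (an executor independent of the package) and return per-table row counts.
run_sql_oracle <- function(script) {
  f <- tempfile(fileext = ".sql")
  writeLines(as.character(script), f)
  py <- paste(
    "import sqlite3, sys, json",
    "con = sqlite3.connect(':memory:')",
    "con.executescript(open(sys.argv[1]).read())",
    "out = {}",
    "for (t,) in con.execute(\"SELECT name FROM sqlite_master WHERE type='table'\").fetchall():",
    "    out[t] = con.execute('SELECT COUNT(*) FROM \"%s\"' % t).fetchone()[0]",
    "print(json.dumps(out))",
    sep = "\n")
  pf <- tempfile(fileext = ".py")
  writeLines(py, pf)
  out <- system2("python", c(pf, f), stdout = TRUE, stderr = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

# Parse an OWL document with rdflib (independent reference parser) and
# return its triples as a sorted character vector of "s|p|o" keys (literals
# rendered with their datatype tag collapsed like the package does).
rdflib_triples <- function(doc_text) {
  f <- tempfile(fileext = ".owl")
  writeLines(doc_text, f)
  py <- paste(
    "import sys",
    "from rdflib import Graph, Literal, URIRef",
    "from rdflib.namespace import XSD",
    "g = Graph(); g.parse(sys.argv[1], format='xml')",
    "tagmap = {str(XSD.string): 'string', None: 'string',",
    "  str(XSD.integer): 'integer', str(XSD.int): 'integer',",
    "  str(XSD.long): 'integer', str(XSD.float): 'float',",
    "  str(XSD.double): 'float', str(XSD.decimal): 'float',",
    "  str(XSD.boolean): 'boolean', str(XSD.date): 'date',",
    "  str(XSD.dateTime): 'datetime'}",
    "for s, p, o in g:",
    "    if isinstance(o, Literal):",
    "        dt = str(o.datatype) if o.datatype else None",
    "        obj = 'L' + tagmap.get(dt, 'string') + ':' + str(o)",
    "    else:",
    "        obj = str(o)",
    "    print(str(s) + '|' + str(p) + '|' + obj)",
    sep = "\n")
  pf <- tempfile(fileext = ".py")
  writeLines(py, pf)
  sort(system2("python", c(pf, f), stdout = TRUE))
}

ss_keys <- function(ss) {
  s <- as.data.frame(ss)
  sort(paste0(s$subject, "|", s$predicate, "|",
              ifelse(s$obj_kind == "literal",
                     paste0("L", s$lit_type, ":", s$object), s$object)))
}

# A tiny hand-built application used where the full generator would get in
# the way: three forms (Case -> Lab via a directly-dependent menu link,
# Case -> Note via a plain one), one coded option list, one Reportable form.
tiny_app <- function(ns = "http://example.org/tinyreg") {
  A <- function(l) paste0(ns, "#", l)
  mm <- ontoreg::mm_ns()
  M <- function(l) paste0(mm, l)
  rdf <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  rdfs_sub <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
  rdfs_dom <- "http://www.w3.org/2000/01/rdf-schema#domain"
  rdfs_rng <- "http://www.w3.org/2000/01/rdf-schema#range"
  rdfs_lab <- "http://www.w3.org/2000/01/rdf-schema#label"
  owl <- "http://www.w3.org/2002/07/owl#"
  xsd <- "http://www.w3.org/2001/XMLSchema#"
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- ontoreg::stmt(...)
  addl <- function(s, p, o, t) rows[[length(rows) + 1L]] <<-
    ontoreg::stmt(s, p, as.character(o), "literal", t)
  add(ns, rdf, paste0(owl, "Ontology"))
  add(A("App"), rdf, paste0(owl, "Class"))
  add(A("App"), rdf, M("Application"))
  for (d in c("Case", "Lab", "Note")) {
    add(A(d), rdf, paste0(owl, "Class"))
    add(A(d), rdf, M("DataStructure"))
    add(A(d), rdfs_sub, M("ApplicationItem"))
  }
  add(A("Lab"), rdfs_sub, M("Reportable"))
  # Case fields: id (code), severity (coded radio), onset (date), notes
  add(A("code"), rdf, paste0(owl, "DatatypeProperty"))
  add(A("code"), rdf, M("SingleCell"))
  add(A("code"), rdfs_dom, A("Case"))
  add(A("code"), rdfs_rng, paste0(xsd, "string"))
  addl(A("code"), M("webRow"), 1, "integer")
  addl(A("code"), M("webColumn"), 1, "integer")
  addl(A("code"), M("webIdProperty"), "true", "boolean")
  addl(A("code"), M("webMandatoryProperty"), "true", "boolean")
  addl(A("code"), M("webDescriptionProperty"), "true", "boolean")
  add(A("severity"), rdf, paste0(owl, "ObjectProperty"))
  add(A("severity"), rdf, M("RadioButton"))
  add(A("severity"), rdfs_dom, A("Case"))
  add(A("severity"), rdfs_rng, A("SeverityValues"))
  addl(A("severity"), M("webRow"), 2, "integer")
  addl(A("severity"), M("webColumn"), 1, "integer")
  add(A("SeverityValues"), rdf, paste0(owl, "Class"))
  add(A("SeverityValues"), rdfs_sub, M("CodedValues"))
  for (i in 1:3) {
    o <- A(paste0("sev", i))
    add(o, rdf, A("SeverityValues"))
    addl(o, rdfs_lab, c("Mild", "Moderate", "Severe")[i], "string")
    addl(o, M("order"), i, "integer")
    addl(o, M("code"), sprintf("S%d", i), "string")
  }
  add(A("onset"), rdf, paste0(owl, "DatatypeProperty"))
  add(A("onset"), rdf, M("SingleCell"))
  add(A("onset"), rdfs_dom, A("Case"))
  add(A("onset"), rdfs_rng, paste0(xsd, "date"))
  addl(A("onset"), M("webRow"), 2, "integer")
  addl(A("onset"), M("webColumn"), 2, "integer")
  add(A("frozen"), rdf, paste0(owl, "DatatypeProperty"))
  add(A("frozen"), rdf, M("SingleCell"))
  add(A("frozen"), rdfs_dom, A("Case"))
  add(A("frozen"), rdfs_rng, paste0(xsd, "string"))
  addl(A("frozen"), M("webRow"), 3, "integer")
  addl(A("frozen"), M("webColumn"), 1, "integer")
  addl(A("frozen"), M("webEditionDisabled"), "true", "boolean")
  add(A("pw"), rdf, paste0(owl, "DatatypeProperty"))
  add(A("pw"), rdf, M("Password"))
  add(A("pw"), rdfs_dom, A("Case"))
  add(A("pw"), rdfs_rng, paste0(xsd, "string"))
  addl(A("pw"), M("webRow"), 3, "integer")
  addl(A("pw"), M("webColumn"), 2, "integer")
  # Lab fields
  add(A("lab_id"), rdf, paste0(owl, "DatatypeProperty"))
  add(A("lab_id"), rdf, M("SingleCell"))
  add(A("lab_id"), rdfs_dom, A("Lab"))
  add(A("lab_id"), rdfs_rng, paste0(xsd, "string"))
  addl(A("lab_id"), M("webRow"), 1, "integer")
  addl(A("lab_id"), M("webColumn"), 1, "integer")
  addl(A("lab_id"), M("webIdProperty"), "true", "boolean")
  addl(A("lab_id"), M("webDescriptionProperty"), "true", "boolean")
  add(A("titer"), rdf, paste0(owl, "DatatypeProperty"))
  add(A("titer"), rdf, M("SingleCell"))
  add(A("titer"), rdfs_dom, A("Lab"))
  add(A("titer"), rdfs_rng, paste0(xsd, "float"))
  addl(A("titer"), M("webRow"), 1, "integer")
  addl(A("titer"), M("webColumn"), 2, "integer")
  # Note fields
  add(A("note_id"), rdf, paste0(owl, "DatatypeProperty"))
  add(A("note_id"), rdf, M("SingleCell"))
  add(A("note_id"), rdfs_dom, A("Note"))
  add(A("note_id"), rdfs_rng, paste0(xsd, "string"))
  addl(A("note_id"), M("webRow"), 1, "integer")
  addl(A("note_id"), M("webColumn"), 1, "integer")
  addl(A("note_id"), M("webIdProperty"), "true", "boolean")
  addl(A("note_id"), M("webDescriptionProperty"), "true", "boolean")
  # menus: Lab directly dependent on Case, Note not
  add(A("menu_lab"), rdf, paste0(owl, "ObjectProperty"))
  add(A("menu_lab"), rdf, M("MenuItem"))
  add(A("menu_lab"), rdfs_dom, A("Case"))
  add(A("menu_lab"), rdfs_rng, A("Lab"))
  addl(A("menu_lab"), rdfs_lab, "Laboratory", "string")
  addl(A("menu_lab"), M("webDirectlyDependent"), "true", "boolean")
  add(A("menu_note"), rdf, paste0(owl, "ObjectProperty"))
  add(A("menu_note"), rdf, M("MenuItem"))
  add(A("menu_note"), rdfs_dom, A("Case"))
  add(A("menu_note"), rdfs_rng, A("Note"))
  addl(A("menu_note"), rdfs_lab, "Notes", "string")
  # extractions
  add(A("ex_case"), rdf, M("DataExtraction"))
  add(A("ex_case"), M("extractionClass"), A("Case"))
  addl(A("ex_case"), M("recursive"), "true", "boolean")
  add(A("ex_lab"), rdf, M("DataExtraction"))
  add(A("ex_lab"), M("extractionClass"), A("Lab"))
  addl(A("ex_lab"), M("recursive"), "false", "boolean")
  ontoreg::statement_set(rows, ns)
}

tiny_ns <- "http://example.org/tinyreg"
tiny <- function(l) paste0(tiny_ns, "#", l)

fresh_tiny_repo <- function() {
  repo <- init_repository()
  upload_ontology(repo, tiny_app())
  repo
}
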