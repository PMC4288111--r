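test_that("a minimal ontology header parses to one typing statement", {
  doc <- serialize_owl(statement_set(
    stmt("http://ex.org/o", "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
         "http://www.w3.org/2002/07/owl#Ontology"), "http://ex.org/o"))
  ss <- parse_owl(doc)
  expect_equal(nrow(ss), 1L)
  expect_identical(ss_ontology_iri(ss), "http://ex.org/o")
  expect_length(ss_imports(ss), 0L)
})

test_that("a class with a typed property classifies as the rules demand", {
  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  ss <- statement_set(rbind(
    stmt("http://ex.org/o", rdf_type, "http://www.w3.org/2002/07/owl#Ontology"),
    stmt("http://ex.org/o#Case", rdf_type,
         "http://www.w3.org/2002/07/owl#Class"),
    stmt("http://ex.org/o#age", rdf_type,
         "http://www.w3.org/2002/07/owl#DatatypeProperty"),
    stmt("http://ex.org/o#age", "http://www.w3.org/2000/01/rdf-schema#domain",
         "http://ex.org/o#Case"),
    stmt("http://ex.org/o#age", "http://www.w3.org/2000/01/rdf-schema#range",
         "http://www.w3.org/2001/XMLSchema#integer")), "http://ex.org/o")
  k <- classify_resources(ss)
  expect_identical(unname(k["http://ex.org/o#Case"]), "named_class")
  expect_identical(unname(k["http://ex.org/o#age"]), "datatype_property")
  expect_identical(unname(k["http://ex.org/o"]), "ontology")
  # the domain/range statements survive the round trip
  back <- parse_owl(serialize_owl(ss))
  expect_true(ss_equal(ss, back))
  # cross-check the parsed statement list against an independent OWL parser
  expect_identical(ss_keys(parse_owl(serialize_owl(ss))),
                   rdflib_triples(serialize_owl(ss)))
})

test_that("metaclass promotion follows instances that are themselves classes", {
  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  owl_class <- "http://www.w3.org/2002/07/owl#Class"
  ss <- statement_set(rbind(
    stmt("http://ex#DataStructure", rdf_type, owl_class),
    stmt("http://ex#Case", rdf_type, owl_class),
    stmt("http://ex#Case", rdf_type, "http://ex#DataStructure"),
    stmt("http://ex#c1", rdf_type, "http://ex#Case")))
  k <- classify_resources(ss)
  expect_identical(unname(k["http://ex#DataStructure"]), "metaclass")
  expect_identical(unname(k["http://ex#Case"]), "named_class")
  expect_identical(unname(k["http://ex#c1"]), "individual")
})

test_that("contradictory typing raises a validation error naming the resource", {
  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  ss <- statement_set(rbind(
    stmt("http://ex#X", rdf_type, "http://www.w3.org/2002/07/owl#Class"),
    stmt("http://ex#X", rdf_type,
         "http://www.w3.org/2002/07/owl#DatatypeProperty")))
  expect_error(classify_resources(ss), "contradictory.*http://ex#X")
})

test_that("round trips hold for generated ontologies in both dialects", {
  for (seed in 1:3) {
    ss <- generate_registry(registry_params(seed = seed,
                                            n_data_structures = 4,
                                            fields_per_structure = c(3, 6)))
    for (dialect in c("rdfxml", "turtle")) {
      doc <- serialize_owl(ss, dialect)
      expect_identical(doc, serialize_owl(ss, dialect))  # deterministic
      back <- parse_owl(doc, dialect)
      expect_true(ss_equal(ss, back))
      expect_identical(ss_ontology_iri(back), ss_ontology_iri(ss))
      expect_identical(ss_imports(back), ss_imports(ss))
    }
  }
})

test_that("blank nodes round-trip modulo relabeling", {
  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  ss <- statement_set(rbind(
    stmt("_:zzz", rdf_type, "http://ex#Case"),
    stmt("http://ex#c", "http://ex#linked", "_:zzz"),
    stmt("http://ex#o", rdf_type, "http://www.w3.org/2002/07/owl#Ontology")),
    "http://ex#o")
  for (dialect in c("rdfxml", "turtle")) {
    back <- parse_owl(serialize_owl(ss, dialect), dialect)
    expect_true(ss_equal(ss, back))
  }
})

test_that("malformed documents and unsupported datatypes are rejected", {
  expect_error(parse_owl("<rdf:RDF", "rdfxml"), "parse error")
  expect_error(parse_owl("this is not turtle .", "turtle"), "parse error")
  bad <- paste0('<?xml version="1.0"?>\n',
                '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
                ' xmlns:ex="http://ex#">\n',
                '<rdf:Description rdf:about="http://ex#x">',
                '<ex:p rdf:datatype="http://www.w3.org/2001/XMLSchema#hexBinary">',
                'ff</ex:p></rdf:Description></rdf:RDF>')
  expect_error(parse_owl(bad), "unsupported literal datatype.*hexBinary")
  expect_error(stmt("http://a#x", "http://a#p", "v", "literal", "hexBinary"),
               "unsupported")
})

test_that("import closure orders imported ontologies before importers", {
  header <- function(iri, imports = character(0)) {
    rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
    rows <- list(stmt(iri, rdf_type, "http://www.w3.org/2002/07/owl#Ontology"))
    for (im in imports) {
      rows[[length(rows) + 1L]] <-
        stmt(iri, "http://www.w3.org/2002/07/owl#imports", im)
    }
    statement_set(rows, iri)
  }
  lib <- list(
    "http://x/A" = header("http://x/A", c("http://x/B", "http://x/C")),
    "http://x/B" = header("http://x/B", "http://x/D"),
    "http://x/C" = header("http://x/C", "http://x/D"),
    "http://x/D" = header("http://x/D"))
  resolver <- function(iri) lib[[iri]]

  # no imports
  expect_length(import_closure(lib[["http://x/D"]], resolver), 1L)
  # chain: C before B before A (topological order)
  chain <- list("http://x/B" = header("http://x/B", "http://x/C"),
                "http://x/C" = header("http://x/C"))
  got <- import_closure(header("http://x/A", "http://x/B"),
                        function(iri) chain[[iri]])
  expect_identical(vapply(got, ss_ontology_iri, character(1)),
                   c("http://x/C", "http://x/B", "http://x/A"))
  # diamond: D exactly once, before B and C
  got <- import_closure(lib[["http://x/A"]], resolver)
  iris <- vapply(got, ss_ontology_iri, character(1))
  expect_identical(sum(iris == "http://x/D"), 1L)
  expect_lt(match("http://x/D", iris), match("http://x/B", iris))
  expect_lt(match("http://x/D", iris), match("http://x/C", iris))
  expect_identical(iris[length(iris)], "http://x/A")
  # unresolvable and cyclic imports fail loudly
  expect_error(import_closure(header("http://x/A", "http://x/Z"), resolver),
               "unresolvable import.*http://x/Z")
  cyc <- list("http://x/P" = header("http://x/P", "http://x/Q"),
              "http://x/Q" = header("http://x/Q", "http://x/P"))
  expect_error(import_closure(cyc[["http://x/P"]],
                              function(iri) cyc[[iri]]), "cycle")
})
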