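rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
owl_class <- "http://www.w3.org/2002/07/owl#Class"

test_that("a fresh repository holds exactly the metamodel and is idempotent", {
  dir <- tempfile("repo")
  repo <- init_repository(dir)
  mm <- metamodel_statements()
  st <- download_ontology(repo, "http://ontoreg.org/ns/metamodel")
  expect_true(ss_equal(mm, st))
  n0 <- physical_row_count(repo)
  repo2 <- init_repository(dir)          # second call: open, not re-create
  expect_identical(physical_row_count(repo2), n0)
})

test_that("schema corruption and version mismatches are detected", {
  dir <- tempfile("repo")
  init_repository(dir)
  for (tab in c("statements", "resources", "classes", "value_string",
                "subclass_edges")) {
    broken <- tempfile("broken")
    dir.create(broken)
    file.copy(list.files(dir, full.names = TRUE), broken)
    unlink(file.path(broken, paste0(tab, ".tsv")))
    expect_error(repo_open(broken), paste0("missing table.*", tab))
  }
  versioned <- tempfile("ver")
  dir.create(versioned)
  file.copy(list.files(dir, full.names = TRUE), versioned)
  writeLines('{"schema_version":"99","tables":[]}',
             file.path(versioned, "meta.json"))
  expect_error(repo_open(versioned), "incompatible.*migrate")
})

test_that("a persisted repository reopens with identical structural state", {
  dir <- tempfile("repo")
  repo <- init_repository(dir)
  upload_ontology(repo, tiny_app())
  create_instance(repo, tiny("Case"),
                  list(code = "C1", severity = "Mild", onset = "2011-02-03"))
  repo_save(repo)
  back <- repo_open(dir)
  expect_length(structural_diff(structural_state(repo),
                                structural_state(back)), 0L)
  # the reopened repository is fully operational
  id <- create_instance(back, tiny("Case"), list(code = "C2"))
  expect_true(id > 0)
})

test_that("asserting a class creates its resource and class rows once", {
  repo <- init_repository()
  eff <- assert_statement(repo, stmt("http://a#C", rdf_type, owl_class),
                          "http://a")
  expect_identical(unname(eff$inserted["statements"]), 1L)
  expect_identical(unname(eff$inserted["classes"]), 1L)
  id <- res_resolve(repo, "http://a#C")
  expect_true(id %in% structural_state(repo)$classes)
  # duplicate assert is a zero-effect no-op
  eff2 <- assert_statement(repo, stmt("http://a#C", rdf_type, owl_class),
                           "http://a")
  expect_identical(sum(eff2$inserted) + sum(eff2$flagged), 0L)
})

test_that("contradictory typing is rejected with the statements table unchanged", {
  repo <- init_repository()
  assert_statement(repo, stmt("http://a#C", rdf_type, owl_class), "http://a")
  n0 <- physical_row_count(repo)
  expect_error(assert_statement(repo, stmt("http://a#C", rdf_type,
    "http://www.w3.org/2002/07/owl#DatatypeProperty"), "http://a"),
    "contradictory")
  expect_identical(physical_row_count(repo), n0)
  expect_length(structural_diff(structural_state(repo),
                                rebuild_structural(repo)), 0L)
})

test_that("retraction soft-deletes: live content reverts, physical rows grow", {
  repo <- init_repository()
  base <- structural_state(repo)
  n0 <- physical_row_count(repo)
  assert_statement(repo, stmt("http://a#C", rdf_type, owl_class), "http://a")
  retract_statement(repo, stmt("http://a#C", rdf_type, owl_class))
  st <- structural_state(repo)
  expect_identical(st$classes, base$classes)
  expect_gt(physical_row_count(repo), n0)
  expect_error(retract_statement(repo, stmt("http://a#C", rdf_type,
                                            owl_class)), "not present")
})

test_that("consistency guards refuse retractions that orphan live data", {
  repo <- init_repository()
  assert_statement(repo, stmt("http://a#C", rdf_type, owl_class), "http://a")
  assert_statement(repo, stmt("http://a#i", rdf_type, "http://a#C"), "http://a")
  before <- structural_state(repo)
  expect_error(retract_statement(repo, stmt("http://a#C", rdf_type,
                                            owl_class)), "live instances")
  expect_length(structural_diff(structural_state(repo), before), 0L)
  # property with live values is guarded symmetrically
  assert_statement(repo, stmt("http://a#p", rdf_type,
    "http://www.w3.org/2002/07/owl#DatatypeProperty"), "http://a")
  assert_statement(repo, stmt("http://a#i", "http://a#p", "42", "literal",
                              "integer"), "http://a")
  expect_error(retract_statement(repo, stmt("http://a#p", rdf_type,
    "http://www.w3.org/2002/07/owl#DatatypeProperty")), "live values")
})

test_that("value rows land in the table of the declared range", {
  repo <- init_repository()
  ns <- "http://a"
  assert_statement(repo, stmt("http://a#p", rdf_type,
    "http://www.w3.org/2002/07/owl#DatatypeProperty"), ns)
  # no declared range yet: string hosting with a warning in the effect
  eff <- assert_statement(repo, stmt("http://a#i", "http://a#p", "7",
                                     "literal", "integer"), ns)
  expect_match(eff$warnings, "no declared range")
  expect_identical(nrow(structural_state(repo)$values$value_integer), 0L)
  # declaring the range re-places existing live values (order independence)
  assert_statement(repo, stmt("http://a#p",
    "http://www.w3.org/2000/01/rdf-schema#range",
    "http://www.w3.org/2001/XMLSchema#integer"), ns)
  st <- structural_state(repo)
  expect_identical(nrow(st$values$value_integer), 1L)
  expect_length(structural_diff(st, rebuild_structural(repo)), 0L)
})

test_that("random assert/retract interleavings match the from-scratch rebuild", {
  set.seed(42)
  repo <- init_repository()
  snap <- ontoreg:::repo_snapshot(repo)
  for (trial in 1:15) {
    ontoreg:::repo_restore(repo, snap)
    ss <- generate_registry(registry_params(
      seed = 1000 + trial, n_data_structures = sample(2:4, 1),
      fields_per_structure = c(2, 5)))
    s <- as.data.frame(ss)[sample(seq_len(nrow(ss))), , drop = FALSE]
    n <- min(nrow(s), sample(40:120, 1))
    asserted <- list()
    rows_before <- physical_row_count(repo)
    for (i in seq_len(n)) {
      row <- s[i, , drop = FALSE]
      ok <- tryCatch({
        assert_statement(repo, row, ns = ss_ontology_iri(ss)); TRUE
      }, error = function(e) FALSE)
      if (ok) asserted[[length(asserted) + 1L]] <- row
      if (length(asserted) && stats::runif(1) < 0.25) {
        j <- sample(length(asserted), 1)
        ok <- tryCatch({
          retract_statement(repo, asserted[[j]]); TRUE
        }, error = function(e) FALSE)
        if (ok) asserted[[j]] <- NULL
      }
      expect_gte(physical_row_count(repo), rows_before)
      rows_before <- physical_row_count(repo)
    }
    expect_length(structural_diff(structural_state(repo),
                                  rebuild_structural(repo)), 0L)
  }
})

test_that("resource ids are monotone and never reassigned", {
  repo <- init_repository()
  res <- repo$tables$resources
  ids0 <- ontoreg:::gtab_get(res, "id", seq_len(ontoreg:::gtab_n(res)))
  expect_identical(ids0, seq_along(ids0))
  assert_statement(repo, stmt("http://a#C", rdf_type, owl_class), "http://a")
  retract_statement(repo, stmt("http://a#C", rdf_type, owl_class))
  assert_statement(repo, stmt("http://a#D", rdf_type, owl_class), "http://a")
  expect_gt(res_resolve(repo, "http://a#D"), res_resolve(repo, "http://a#C"))
})

test_that("subsumption and sibling queries answer through the index", {
  repo <- init_repository()
  ns <- "http://t"
  sub <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
  for (cl in c("Root", "Mid", "Leaf")) {
    assert_statement(repo, stmt(paste0("http://t#", cl), rdf_type, owl_class),
                     ns)
  }
  assert_statement(repo, stmt("http://t#Mid", sub, "http://t#Root"), ns)
  assert_statement(repo, stmt("http://t#Leaf", sub, "http://t#Mid"), ns)
  root <- res_resolve(repo, "http://t#Root")
  mid <- res_resolve(repo, "http://t#Mid")
  leaf <- res_resolve(repo, "http://t#Leaf")
  expect_identical(subclasses_of(repo, root), mid)
  expect_setequal(subclasses_of(repo, root, transitive = TRUE), c(mid, leaf))
  expect_length(subclasses_of(repo, leaf, transitive = TRUE), 0L)
  expect_setequal(superclasses_of(repo, leaf), c(root, mid))
  # transitive instance retrieval unions over descendant classes
  assert_statement(repo, stmt("http://t#i1", rdf_type, "http://t#Mid"), ns)
  assert_statement(repo, stmt("http://t#i2", rdf_type, "http://t#Leaf"), ns)
  expect_length(instances_of(repo, root), 0L)
  expect_setequal(instances_of(repo, root, transitive = TRUE),
                  c(res_resolve(repo, "http://t#i1"),
                    res_resolve(repo, "http://t#i2")))
  expect_error(subclasses_of(repo, "http://t#Nope"), "unknown resource")
})

test_that("random taxonomies answer transitive queries like the recursive oracle", {
  set.seed(7)
  repo <- init_repository()
  ns <- "http://tax"
  sub <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
  edges <- generate_hierarchy(hierarchy_params(n_classes = 120,
                                               multiparent_fraction = 0.08,
                                               seed = 99))
  iri_of <- function(i) paste0("http://tax#K", i)
  for (i in 1:120) {
    assert_statement(repo, stmt(iri_of(i), rdf_type, owl_class), ns)
  }
  for (i in seq_len(nrow(edges))) {
    assert_statement(repo, stmt(iri_of(edges$child[i]), sub,
                                iri_of(edges$parent[i])), ns)
  }
  orc <- closure_oracle(edges)
  base <- res_resolve(repo, iri_of(1)) - 1L
  for (q in sample(1:120, 25)) {
    got <- sort(subclasses_of(repo, iri_of(q), transitive = TRUE)) - base
    expect_identical(got, orc$descendants(q))
    got_a <- sort(superclasses_of(repo, iri_of(q))) - base
    expect_identical(got_a, orc$ancestors(q))
  }
})

test_that("upload replace refuses to drop a class that still has instances", {
  repo <- fresh_tiny_repo()
  create_instance(repo, tiny("Lab"), list(lab_id = "L1"))
  app <- tiny_app()
  pruned <- app[!(app$subject == tiny("Lab") | app$object == tiny("Lab")), ,
                drop = FALSE]
  pruned <- statement_set(pruned, ss_ontology_iri(app))
  before <- structural_state(repo)
  expect_error(upload_ontology(repo, pruned, mode = "replace"),
               "refused")
  expect_length(structural_diff(structural_state(repo), before), 0L)
})

test_that("multi-ontology storage keeps import relations queryable", {
  header <- function(iri, imports = character(0), extra = NULL) {
    rows <- list(stmt(iri, rdf_type, "http://www.w3.org/2002/07/owl#Ontology"))
    for (im in imports) {
      rows[[length(rows) + 1L]] <-
        stmt(iri, "http://www.w3.org/2002/07/owl#imports", im)
    }
    rows[[length(rows) + 1L]] <-
      stmt(paste0(iri, "#C"), rdf_type, owl_class)
    statement_set(rows, iri)
  }
  lib <- list("http://x/B" = header("http://x/B", "http://x/D"),
              "http://x/C" = header("http://x/C", "http://x/D"),
              "http://x/D" = header("http://x/D"))
  repo <- init_repository()
  upload_ontology(repo, header("http://x/A", c("http://x/B", "http://x/C")),
                  with_imports = TRUE, resolver = function(iri) lib[[iri]])
  expect_true(all(c("http://x/A", "http://x/B", "http://x/C", "http://x/D")
                  %in% loaded_namespaces(repo)))
  just_a <- download_ontology(repo, "http://x/A")
  with_imp <- download_ontology(repo, "http://x/A", with_imports = TRUE)
  expect_gt(nrow(with_imp), nrow(just_a))
  expect_true(all(ss_keys(just_a) %in% ss_keys(with_imp)))
  expect_true(paste0("http://x/D#C") %in% with_imp$subject)
  expect_error(download_ontology(repo, "http://nope"),
               "not loaded.*http://x/A")
})
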