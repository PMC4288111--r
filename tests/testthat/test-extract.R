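xsd_path <- system.file("schema", "extraction.xsd", package = "ontoreg")

test_that("an extraction over zero instances is an empty, schema-valid document", {
  repo <- fresh_tiny_repo()
  docs <- run_extractions(repo, tiny_ns)
  expect_length(docs, 2L)
  d <- xml2::read_xml(docs[[1]])
  expect_length(xml2::xml_find_all(d, "/extraction/record"), 0L)
  expect_true(xml2::xml_validate(d, xml2::read_xml(xsd_path)))
})

test_that("recursive extraction nests dependents; flat extraction references them", {
  repo <- fresh_tiny_repo()
  dns <- paste0(tiny_ns, "/data")
  case <- create_instance(repo, tiny("Case"),
                          list(code = "C1", severity = "Severe",
                               pw = "secret"))
  labs <- vapply(1:3, function(i) {
    l <- create_instance(repo, tiny("Lab"),
                         list(lab_id = paste0("L", i), titer = i * 1.5))
    assert_statement(repo, stmt(res_iri_of(repo, case), tiny("menu_lab"),
                                res_iri_of(repo, l), "iri"), dns)
    l
  }, integer(1))
  docs <- run_extractions(repo, tiny_ns)
  rec <- xml2::read_xml(docs[[tiny("ex_case")]])    # recursive spec
  expect_true(xml2::xml_validate(rec, xml2::read_xml(xsd_path)))
  expect_length(xml2::xml_find_all(rec, "/extraction/record"), 1L)
  nested <- xml2::xml_find_all(rec, "//record/field/record")
  expect_length(nested, 3L)
  # coded option values carry label text plus the code attribute
  sev <- xml2::xml_find_first(rec, "//field[@name='severity']")
  expect_identical(xml2::xml_text(sev), "Severe")
  expect_identical(xml2::xml_attr(sev, "code"), "S3")
  # no password data in any export
  expect_false(grepl("secret", docs[[tiny("ex_case")]], fixed = TRUE))
  expect_false(grepl("\"pw\"|'pw'", docs[[tiny("ex_case")]]))
  flat <- xml2::read_xml(docs[[tiny("ex_lab")]])    # non-recursive spec
  expect_length(xml2::xml_find_all(flat, "/extraction/record"), 3L)
  expect_length(xml2::xml_find_all(flat, "//record/field/record"), 0L)
  # the flat view of the case would hold refs; check via a mutated spec
  app <- tiny_app()
  flat_app <- as.data.frame(app)
  sel <- flat_app$subject == tiny("ex_case") &
    flat_app$predicate == paste0(ontoreg::mm_ns(), "recursive")
  flat_app$object[sel] <- "false"
  upload_ontology(repo, statement_set(flat_app, tiny_ns), mode = "replace")
  docs2 <- run_extractions(repo, tiny_ns)
  flat_case <- xml2::read_xml(docs2[[tiny("ex_case")]])
  refs <- xml2::xml_find_all(flat_case, "//field[@ref]")
  expect_length(refs, 3L)
  expect_setequal(as.integer(xml2::xml_attr(refs, "ref")), labs)
})

test_that("an application without extraction specs reports nothing to extract", {
  repo <- init_repository()
  app <- tiny_app()
  pruned <- as.data.frame(app)
  pruned <- pruned[!grepl("#ex_", pruned$subject), , drop = FALSE]
  upload_ontology(repo, statement_set(pruned, tiny_ns))
  expect_error(run_extractions(repo, tiny_ns), "nothing to extract")
})

test_that("record counts equal live instance counts, and deletions drop out", {
  repo <- init_repository()
  app <- generate_registry(registry_params(seed = 21, n_data_structures = 4,
                                           fields_per_structure = c(3, 6)))
  ns <- ss_ontology_iri(app)
  upload_ontology(repo, app)
  pop <- populate_instances(repo, ns, registry_params(seed = 21, n_cases = 8))
  model <- compile_forms(app)
  case_id <- res_resolve(repo, model$case_root)
  delete_instance(repo, pop$cases[3])
  docs <- run_extractions(repo, ns)
  live <- length(instances_of(repo, case_id))
  expect_identical(live, 7L)
  rec <- xml2::read_xml(docs[[1]])
  expect_length(xml2::xml_find_all(rec, "/extraction/record"), live)
})

test_that("the SQL mirror executes on an empty database with matching counts", {
  repo <- init_repository()
  app <- generate_registry(registry_params(seed = 22, n_data_structures = 4,
                                           fields_per_structure = c(3, 6)))
  ns <- ss_ontology_iri(app)
  upload_ontology(repo, app)
  # definitions only before any instance exists
  empty_script <- export_sql(repo, ns)
  expect_false(grepl("INSERT", empty_script, fixed = TRUE))
  counts0 <- run_sql_oracle(empty_script)
  expect_true(all(unlist(counts0) == 0))
  pop <- populate_instances(repo, ns, registry_params(seed = 22, n_cases = 6))
  delete_instance(repo, pop$cases[1])
  script <- export_sql(repo, ns)
  got <- run_sql_oracle(script)
  model <- compile_forms(app)
  for (d in names(model$forms)) {
    tab <- ontoreg:::sql_name(basename(sub(".*#", "", d)))
    expect_identical(got[[tab]],
                     length(instances_of(repo, res_resolve(repo, d))),
                     label = paste("table", tab))
  }
  # deleted case ids never appear in the script
  expect_false(grepl(paste0("VALUES \\(", pop$cases[1], ","), script))
})

test_that("ontoload equals statement-by-statement upload, and is all-or-nothing", {
  for (seed in c(31, 32, 33)) {
    app <- generate_registry(registry_params(seed = seed,
                                             n_data_structures = 3,
                                             fields_per_structure = c(3, 5)))
    r1 <- init_repository(); upload_ontology(r1, app)
    r2 <- init_repository(); ontoload(r2, serialize_owl(app))
    expect_length(structural_diff(structural_state(r1),
                                  structural_state(r2)), 0L)
    expect_true(ss_equal(download_ontology(r2, ss_ontology_iri(app)), app))
  }
  repo <- init_repository()
  n0 <- physical_row_count(repo)
  expect_error(ontoload(repo, "<rdf:RDF"), "parse error")
  expect_error(ontoload(repo, statement_set()), "no ontology header")
  hdr_only <- statement_set(
    stmt("http://e/x", "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
         "http://www.w3.org/2002/07/owl#Ontology"), "http://e/x")
  empty_doc <- statement_set(as.data.frame(hdr_only)[0, ], "http://e/x")
  expect_error(ontoload(repo, empty_doc), "empty document")
  expect_identical(physical_row_count(repo), n0)
})
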