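test_that("compilation builds the menu and one form per DataStructure", {
  app <- generate_registry(registry_params(seed = 1))
  model <- compile_forms(app)
  expect_true(all(c("Previous Manifestations", "Precipitating Factors",
                    "Clinical Manifestations") %in% model$menu$label))
  expect_identical(basename(sub(".*#", "", model$case_root)), "Case")
  expect_length(model$forms,
                length(unique(app$subject[app$object ==
                  paste0(ontoreg::mm_ns(), "DataStructure")])))
  # deterministic rendering
  expect_identical(render_form_model(model),
                   render_form_model(compile_forms(app)))
})

test_that("a DataStructure with no fields compiles to an empty grid", {
  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  app <- tiny_app()
  extra <- rbind(
    stmt(tiny("Empty"), rdf_type, "http://www.w3.org/2002/07/owl#Class"),
    stmt(tiny("Empty"), rdf_type, paste0(ontoreg::mm_ns(), "DataStructure")),
    stmt(tiny("Empty"), "http://www.w3.org/2000/01/rdf-schema#subClassOf",
         paste0(ontoreg::mm_ns(), "ApplicationItem")),
    stmt(tiny("menu_empty"), rdf_type,
         "http://www.w3.org/2002/07/owl#ObjectProperty"),
    stmt(tiny("menu_empty"), rdf_type, paste0(ontoreg::mm_ns(), "MenuItem")),
    stmt(tiny("menu_empty"), "http://www.w3.org/2000/01/rdf-schema#domain",
         tiny("Case")),
    stmt(tiny("menu_empty"), "http://www.w3.org/2000/01/rdf-schema#range",
         tiny("Empty")))
  app2 <- statement_set(rbind(as.data.frame(app), extra),
                        ss_ontology_iri(app))
  model <- compile_forms(app2)
  expect_true(tiny("Empty") %in% names(model$forms))
  expect_length(model$forms[[tiny("Empty")]]$fields, 0L)
})

test_that("the JSON bundle round-trips and an invalid app is refused", {
  model <- compile_forms(tiny_app())
  json <- render_form_model(model)
  expect_identical(render_form_model(parse_form_model(json)), json)
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_identical(parsed$schema_version, "1.0")
  expect_true(all(vapply(parsed$forms, function(f)
    all(c("data_structure", "fields") %in% names(f)), logical(1))))
  broken <- statement_set(as.data.frame(tiny_app())[-1, ], tiny_ns)
  bad <- validate_application(broken)
  if (!bad$is_valid) expect_error(compile_forms(broken), "invalid")
  html <- render_form_html(model)
  expect_match(html, "<table", fixed = TRUE)
})

test_that("creation enforces the constraint gate in its documented order", {
  repo <- fresh_tiny_repo()
  n0 <- physical_row_count(repo)
  cases <- list(
    list(vals = list(severity = "Mild"), code = "MANDATORY_MISSING"),
    list(vals = list(code = "C1", severity = "Nope", onset = "bad"),
         code = "OPTION_INVALID"),       # options checked before types
    list(vals = list(code = "C1", onset = "bad"), code = "TYPE_MISMATCH"),
    list(vals = list(code = "C1", nosuch = 1), code = "UNKNOWN_FIELD"))
  for (cs in cases) {
    e <- tryCatch(create_instance(repo, tiny("Case"), cs$vals),
                  error = function(e) e)
    expect_identical(reject_code(e), cs$code)
    expect_identical(physical_row_count(repo), n0)  # rejection atomicity
  }
  id <- create_instance(repo, tiny("Case"),
                        list(code = "C1", severity = "Mild",
                             onset = "2015-05-06"))
  e <- tryCatch(create_instance(repo, tiny("Case"), list(code = "C1")),
                error = function(e) e)
  expect_identical(reject_code(e), "ID_NOT_UNIQUE")
  # option accepted by label, code or IRI
  for (v in list("Moderate", "S3", tiny("sev1"))) {
    expect_silent(create_instance(repo, tiny("Case"),
                                  list(code = paste0("C-", v), severity = v)))
  }
})

test_that("notifications fire exactly once per Reportable creation", {
  repo <- fresh_tiny_repo()
  seen <- 0L
  set_notify_hook(repo, function(n) seen <<- seen + 1L)
  create_instance(repo, tiny("Case"), list(code = "C1"))   # not Reportable
  expect_length(notifications(repo), 0L)
  create_instance(repo, tiny("Lab"), list(lab_id = "L1"))  # Reportable
  create_instance(repo, tiny("Lab"), list(lab_id = "L2"))
  expect_length(notifications(repo), 2L)
  expect_identical(seen, 2L)
  expect_identical(notifications(repo)[[1]]$data_structure, tiny("Lab"))
  # a rejected creation emits nothing
  try(create_instance(repo, tiny("Lab"), list(lab_id = "L1")), silent = TRUE)
  expect_length(notifications(repo), 2L)
})

test_that("updates respect edition locks and read back what was written", {
  repo <- fresh_tiny_repo()
  id <- create_instance(repo, tiny("Case"),
                        list(code = "C1", severity = "Mild",
                             onset = "2011-01-01"))
  expect_identical(update_instance(repo, id, list())$rows_changed, 0L)
  e <- tryCatch(update_instance(repo, id, list(frozen = "nope")),
                error = function(e) e)
  expect_identical(reject_code(e), "EDITION_DISABLED")
  e <- tryCatch(update_instance(repo, id, list(code = "")),
                error = function(e) e)
  expect_identical(reject_code(e), "MANDATORY_MISSING")
  set.seed(23)
  for (i in 1:10) {
    newdate <- as.character(as.Date("2010-01-01") + sample.int(2000, 1))
    newsev <- sample(c("Mild", "Moderate", "Severe"), 1)
    update_instance(repo, id, list(onset = newdate, severity = newsev))
    v <- values_of(repo, id, tiny("onset"))
    expect_identical(v$lex, newdate)
    v2 <- values_of(repo, id, tiny("severity"))
    expect_identical(basename(v2$object), basename(resolve <- tiny(
      c(Mild = "sev1", Moderate = "sev2", Severe = "sev3")[[newsev]])))
  }
  invisible(delete_instance(repo, id))
  e <- tryCatch(update_instance(repo, id, list(onset = "2012-01-01")),
                error = function(e) e)
  expect_identical(reject_code(e), "UNKNOWN_INSTANCE")
})

test_that("delete cascades exactly over directly-dependent references", {
  set.seed(31)
  for (trial in 1:6) {
    repo <- fresh_tiny_repo()
    case <- create_instance(repo, tiny("Case"), list(code = "C1"))
    dns <- paste0(tiny_ns, "/data")
    labs <- integer(0); notes <- integer(0)
    for (i in seq_len(sample(1:4, 1))) {
      l <- create_instance(repo, tiny("Lab"), list(lab_id = paste0("L", i)))
      labs <- c(labs, l)
      assert_statement(repo, stmt(res_iri_of(repo, case), tiny("menu_lab"),
                                  res_iri_of(repo, l), "iri"), dns)
    }
    for (i in seq_len(sample(0:2, 1))) {
      nt <- create_instance(repo, tiny("Note"), list(note_id = paste0("N", i)))
      notes <- c(notes, nt)
      assert_statement(repo, stmt(res_iri_of(repo, case), tiny("menu_note"),
                                  res_iri_of(repo, nt), "iri"), dns)
    }
    n0 <- physical_row_count(repo)
    flagged <- delete_instance(repo, case)
    # dependents (labs) cascade; independents (notes) survive
    expect_setequal(flagged, c(case, labs))
    expect_identical(sort(instances_of(repo, tiny("Note"))), sort(notes))
    expect_length(instances_of(repo, tiny("Lab")), 0L)
    expect_gte(physical_row_count(repo), n0)
    expect_error(delete_instance(repo, case), "deleted")
  }
})

test_that("instance lists carry the description columns in grid order", {
  repo <- fresh_tiny_repo()
  expect_identical(nrow(list_instances(repo, tiny("Case"))), 0L)
  ids <- vapply(1:5, function(i)
    create_instance(repo, tiny("Case"), list(code = paste0("C", i))),
    integer(1))
  delete_instance(repo, ids[2])
  delete_instance(repo, ids[4])
  li <- list_instances(repo, tiny("Case"))
  expect_identical(nrow(li), 3L)                 # n created - k deleted
  expect_identical(names(li), c("instance_id", "instance", "code"))
  expect_setequal(li$code, c("C1", "C3", "C5"))
})

test_that("deprecated structures refuse creations; deprecated fields relax checks", {
  repo <- fresh_tiny_repo()
  deprecate(repo, tiny("Note"))
  e <- tryCatch(create_instance(repo, tiny("Note"), list(note_id = "N1")),
                error = function(e) e)
  expect_identical(reject_code(e), "DEPRECATED")
  # deprecating the mandatory id field of Case exempts it at create time
  deprecate(repo, tiny("code"))
  id <- create_instance(repo, tiny("Case"), list(severity = "Mild"))
  expect_true(id > 0)
  e <- tryCatch(update_instance(repo, id, list(code = "C9")),
                error = function(e) e)
  expect_identical(reject_code(e), "DEPRECATED")
})
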