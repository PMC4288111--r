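mm <- ontoreg::mm_ns()
M <- function(l) paste0(mm, l)

drop_stmt <- function(app, subject, predicate = NULL, object = NULL) {
  cond <- app$subject == subject
  if (!is.null(predicate)) cond <- cond & app$predicate == predicate
  if (!is.null(object)) cond <- cond & app$object == object
  statement_set(as.data.frame(app)[!cond, , drop = FALSE],
                ss_ontology_iri(app))
}

add_stmts <- function(app, rows) {
  statement_set(rbind(as.data.frame(app), rows), ss_ontology_iri(app))
}

test_that("the metamodel ships the full widget and facet vocabulary", {
  ss <- metamodel_statements()
  widgets <- ss$subject[ss$predicate ==
                          "http://www.w3.org/2000/01/rdf-schema#subClassOf" &
                          ss$object == M("FormElement")]
  expect_length(widgets, 11L)
  expect_setequal(basename(widgets),
                  c(paste0("metamodel#",
                           c("Checkbox", "Combobox", "Graphic",
                             "HyperlinkProperty", "ImageProperty",
                             "LiteralProperty", "MultilineStringProperty",
                             "RadioButton", "SingleCell", "Password",
                             "SubForm"))))
  facets <- grep("#web", unique(ss$subject), value = TRUE)
  expect_length(facets, 7L)
  # option machinery per the coded-placeholder pattern
  expect_true(any(ss$subject == M("CodedValues") & ss$object ==
                    M("AllowedValues")))
  expect_true(any(ss$subject == M("AllowedValues") & ss$object ==
                    M("OrderedItem")))
  # loads into a fresh repository cleanly (init does exactly this)
  repo <- init_repository()
  expect_true(ss_equal(metamodel_statements(),
                       download_ontology(repo, "http://ontoreg.org/ns/metamodel")))
})

test_that("a registry modeled like the motivating CAPS registry validates", {
  app <- generate_registry(registry_params(seed = 1))
  ds <- app$subject[app$predicate ==
                      "http://www.w3.org/1999/02/22-rdf-syntax-ns#type" &
                      app$object == M("DataStructure")]
  expect_true(all(c("Case", "Precipitating_Factors",
                    "Previous_Manifestations", "Laboratory", "Treatment")
                  %in% basename(sub(".*#", "", ds))))
  report <- validate_application(app)
  expect_true(report$is_valid)
  expect_identical(nrow(report$errors), 0L)
})

test_that("an empty statement set fails only the application-presence rule", {
  report <- validate_application(statement_set())
  expect_false(report$is_valid)
  expect_identical(unique(report$errors$code), "r1")
})

test_that("every validation rule has a mutation that triggers it alone", {
  app <- tiny_app()
  expect_true(validate_application(app)$is_valid)
  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  objprop <- "http://www.w3.org/2002/07/owl#ObjectProperty"
  mutations <- list(
    r1 = function(a) drop_stmt(a, tiny("App"), rdf_type, M("Application")),
    r2 = function(a) drop_stmt(a, tiny("Lab"),
      "http://www.w3.org/2000/01/rdf-schema#subClassOf", M("ApplicationItem")),
    r3 = function(a) drop_stmt(a, tiny("titer"), rdf_type, M("SingleCell")),
    r4 = function(a) drop_stmt(a, tiny("menu_note"), rdf_type, objprop),
    r5 = function(a) add_stmts(
      drop_stmt(a, tiny("titer"), M("webColumn")),
      stmt(tiny("titer"), M("webColumn"), "1", "literal", "integer")),
    r6 = function(a) drop_stmt(a, tiny("severity"),
      "http://www.w3.org/2000/01/rdf-schema#range", tiny("SeverityValues")),
    r7 = function(a) drop_stmt(a, tiny("sev2"), M("code")),
    r8 = function(a) drop_stmt(a, tiny("sev3"), M("order")),
    r10 = function(a) add_stmts(a,
      stmt(tiny("onset"), M("webDirectlyDependent"), "true", "literal",
           "boolean")),
    r11 = function(a) add_stmts(a,
      stmt(tiny("onset"), M("webIdProperty"), "true", "literal", "boolean"))
  )
  for (rule in names(mutations)) {
    report <- validate_application(mutations[[rule]](app))
    expect_false(report$is_valid, label = paste("mutation", rule))
    expect_identical(unique(report$errors$code), rule,
                     label = paste("mutation", rule, "fires exactly itself"))
    expect_identical(nrow(report$warnings), 0L,
                     label = paste("mutation", rule, "no cross-fire warning"))
  }
  # r9 (SubForm) is a warning, not an error
  sub <- add_stmts(app, rbind(
    stmt(tiny("extra"), rdf_type,
         "http://www.w3.org/2002/07/owl#DatatypeProperty"),
    stmt(tiny("extra"), rdf_type, M("SubForm")),
    stmt(tiny("extra"), "http://www.w3.org/2000/01/rdf-schema#domain",
         tiny("Note")),
    stmt(tiny("extra"), M("webRow"), "2", "literal", "integer"),
    stmt(tiny("extra"), M("webColumn"), "1", "literal", "integer")))
  report <- validate_application(sub)
  expect_true(report$is_valid)
  expect_identical(unique(report$warnings$code), "r9")
})

test_that("field specs resolve widgets, facets and ranked options in order", {
  app <- tiny_app()
  specs <- field_specs(app, tiny("Case"))
  locals <- vapply(specs, function(s) s$local, character(1))
  # ordered by (row, column)
  expect_identical(locals, c("code", "severity", "onset", "frozen", "pw"))
  sev <- specs[[2]]
  expect_identical(sev$widget, "RadioButton")
  expect_identical(sev$options$label, c("Mild", "Moderate", "Severe"))
  expect_identical(sev$options$code, c("S1", "S2", "S3"))
  expect_true(attr(sev$options, "coded"))
  expect_true(specs[[1]]$facets$is_id)
  expect_true(specs[[1]]$facets$is_mandatory)   # id implies mandatory
  expect_true(specs[[4]]$facets$edition_disabled)
  expect_error(field_specs(app, tiny("Nope")), "unknown DataStructure")
})

test_that("field ordering matches an independent (row, column) sort oracle", {
  app <- generate_registry(registry_params(seed = 6))
  ds <- unique(app$subject[app$predicate ==
    "http://www.w3.org/1999/02/22-rdf-syntax-ns#type" &
    app$object == M("DataStructure")])
  for (d in ds[1:3]) {
    specs <- field_specs(app, d)
    pos <- t(vapply(specs, function(s)
      c(s$facets$web_row, s$facets$web_column), integer(2)))
    expect_identical(order(pos[, 1], pos[, 2]), seq_len(nrow(pos)))
    # deterministic and total
    locals2 <- vapply(field_specs(app, d), function(s) s$local, character(1))
    expect_identical(vapply(specs, function(s) s$local, character(1)), locals2)
  }
})
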