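# The built-in registry metamodel: the fixed vocabulary of metaclasses,
# classes and facet properties that application ontologies conform to.  An
# application is an instance of the Application metaclass; its forms are
# classes instantiating the DataStructure metaclass (and subclasses of
# ApplicationItem); form fields are properties punned as instances of a
# FormElement subclass; constrained fields range over a subclass of
# AllowedValues whose instances are the options.

METAMODEL_IRI <- "http://ontoreg.org/ns/metamodel"
METAMODEL_VERSION <- "1.0"

# The eleven widget behaviors a form field can have.
FORM_WIDGETS <- c("Checkbox", "Combobox", "Graphic", "HyperlinkProperty",
                  "ImageProperty", "LiteralProperty",
                  "MultilineStringProperty", "RadioButton", "SingleCell",
                  "Password", "SubForm")

# The seven layout/behavior facets of form fields.
FACET_PROPERTIES <- c("webColumn", "webRow", "webDescriptionProperty",
                      "webMandatoryProperty", "webIdProperty",
                      "webEditionDisabled", "webDirectlyDependent")

# Widgets whose values must come from an AllowedValues option list.
CHOICE_WIDGETS <- c("Combobox", "RadioButton")

#' The built-in metamodel as a statement set
#'
#' Fixed, version-tagged, immutable at runtime; pre-loaded into every fresh
#' repository.
#'
#' @return A [statement_set()].
#' @export
metamodel_statements <- function() {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- stmt(...)
  addl <- function(...) rows[[length(rows) + 1L]] <<- lit_stmt(...)
  add(METAMODEL_IRI, IRI_TYPE, IRI_ONTOLOGY)
  addl(METAMODEL_IRI, IRI_VERSION, METAMODEL_VERSION, "string")
  classes <- c("Application", "DataStructure", "ApplicationItem", "MenuItem",
               "FormElement", FORM_WIDGETS, "OrderedItem", "AllowedValues",
               "CodedValues", "Reportable", "DataExtraction")
  for (cl in classes) add(MM(cl), IRI_TYPE, IRI_CLASS)
  for (w in FORM_WIDGETS) add(MM(w), IRI_SUBCLASS, MM("FormElement"))
  add(MM("AllowedValues"), IRI_SUBCLASS, MM("OrderedItem"))
  add(MM("CodedValues"), IRI_SUBCLASS, MM("AllowedValues"))
  dtprop <- function(local, range) {
    add(MM(local), IRI_TYPE, IRI_DTPROP)
    add(MM(local), IRI_RANGE, XSD(range))
  }
  dtprop("webColumn", "integer")
  dtprop("webRow", "integer")
  for (f in c("webDescriptionProperty", "webMandatoryProperty",
              "webIdProperty", "webEditionDisabled", "webDirectlyDependent")) {
    dtprop(f, "boolean")
  }
  dtprop("code", "string")
  add(MM("code"), IRI_DOMAIN, MM("CodedValues"))
  dtprop("order", "integer")
  add(MM("order"), IRI_DOMAIN, MM("OrderedItem"))
  add(MM("extractionClass"), IRI_TYPE, IRI_OBJPROP)
  add(MM("extractionClass"), IRI_DOMAIN, MM("DataExtraction"))
  dtprop("recursive", "boolean")
  add(MM("recursive"), IRI_DOMAIN, MM("DataExtraction"))
  statement_set(rows, METAMODEL_IRI)
}

# ---- graph helpers over a (app + metamodel) statement data.frame -----------

mm_graph <- function(app) {
  df <- rbind(as.data.frame(app), as.data.frame(metamodel_statements()))
  tdf <- df[df$predicate == IRI_TYPE & df$obj_kind != "literal", , drop = FALSE]
  sub <- df[df$predicate == IRI_SUBCLASS & df$obj_kind != "literal", ,
            drop = FALSE]
  list(df = df, tdf = tdf, sub = sub)
}

g_typed <- function(g, cls) unique(g$tdf$subject[g$tdf$object == cls])
g_types <- function(g, x) unique(g$tdf$object[g$tdf$subject == x])

# all (transitive) superclasses of x over rdfs:subClassOf
g_supers <- function(g, x) {
  out <- character(0); frontier <- x
  while (length(frontier)) {
    nxt <- unique(g$sub$object[g$sub$subject %in% frontier])
    frontier <- setdiff(nxt, out)
    out <- union(out, frontier)
  }
  out
}

g_lit <- function(g, s, p) {
  v <- g$df$object[g$df$subject == s & g$df$predicate == p &
                     g$df$obj_kind == "literal"]
  if (length(v)) v[1] else NA_character_
}

g_objs <- function(g, s, p) {
  unique(g$df$object[g$df$subject == s & g$df$predicate == p &
                       g$df$obj_kind != "literal"])
}

g_flag <- function(g, s, p) isTRUE(g_lit(g, s, p) %in% c("true", "1"))

g_int <- function(g, s, p) {
  v <- g_lit(g, s, p)
  if (is.na(v) || !grepl("^[+-]?[0-9]+$", v)) NA_integer_ else as.integer(v)
}

# DataStructures, fields and menu properties of an application graph.
app_structures <- function(g) {
  ds <- sort(g_typed(g, MM("DataStructure")))
  menu_props <- sort(g_typed(g, MM("MenuItem")))
  fields_of <- function(d) {
    f <- unique(g$df$subject[g$df$predicate == IRI_DOMAIN &
                               g$df$object == d])
    sort(setdiff(f, menu_props))
  }
  list(ds = ds, menu_props = menu_props, fields_of = fields_of)
}

field_widget <- function(g, f) {
  w <- intersect(g_types(g, f), MM(FORM_WIDGETS))
  iri_local(w)
}

# ---- validation ------------------------------------------------------------

#' Validate an application ontology against the metamodel
#'
#' Runs the coded conformance rules and returns a structured report; nothing
#' is thrown — all findings are errors or warnings in the report.  Rules:
#' r1 at least one Application instance; r2 form classes instantiate
#' DataStructure and subclass ApplicationItem; r3 each field carries exactly
#' one FormElement widget; r4 menu entries are object properties linking
#' DataStructures; r5 no (row, column) collision within a form; r6 choice
#' fields range over an AllowedValues subclass with options; r7 coded options
#' carry a code; r8 options carry an order rank; r9 SubForm fields are
#' unsupported (warning); r10 the directly-dependent facet only on object
#' properties; r11 at most one id field per form.  Missing webRow/webColumn
#' on a field is reported under the separate code `layout`.
#'
#' @param app A [statement_set()] (the application's model statements).
#' @return A `validation_report` with data.frames `errors` and `warnings` and
#'   the flag `is_valid`.
#' @export
validate_application <- function(app) {
  g <- mm_graph(app)
  errors <- list(); warnings <- list()
  err <- function(code, subject, message) {
    errors[[length(errors) + 1L]] <<- data.frame(
      code = code, subject = subject, message = message,
      stringsAsFactors = FALSE)
  }
  warn <- function(code, subject, message) {
    warnings[[length(warnings) + 1L]] <<- data.frame(
      code = code, subject = subject, message = message,
      stringsAsFactors = FALSE)
  }
  apps <- g_typed(g, MM("Application"))
  if (!length(apps)) {
    err("r1", NA_character_, "no instance of the Application metaclass")
  }
  parts <- app_structures(g)
  ds <- parts$ds
  for (d in ds) {
    if (!(MM("ApplicationItem") %in% g_supers(g, d))) {
      err("r2", d, "DataStructure is not a subclass of ApplicationItem")
    }
  }
  av_subclasses <- unique(g$sub$subject[
    vapply(g$sub$subject, function(x)
      MM("AllowedValues") %in% g_supers(g, x), logical(1))])
  av_subclasses <- setdiff(av_subclasses, MM(c("AllowedValues", "CodedValues")))
  for (d in ds) {
    fields <- parts$fields_of(d)
    seen_rc <- character(0)
    id_fields <- character(0)
    for (f in fields) {
      w <- field_widget(g, f)
      if (length(w) != 1L) {
        err("r3", f, paste0("field must instantiate exactly one FormElement ",
                            "subclass (found ", length(w), ")"))
      }
      if (length(w) == 1L && w == "SubForm") {
        warn("r9", f, "SubForm fields are unsupported and will be skipped")
      }
      row <- g_int(g, f, MM("webRow")); col <- g_int(g, f, MM("webColumn"))
      if (is.na(row) || is.na(col)) {
        err("layout", f, "field lacks a webRow/webColumn grid position")
      } else {
        rc <- paste0(row, ",", col)
        if (rc %in% seen_rc) {
          err("r5", f, paste0("grid position (", rc, ") already used in <",
                              d, ">"))
        }
        seen_rc <- c(seen_rc, rc)
      }
      if (length(w) == 1L && w %in% CHOICE_WIDGETS) {
        rng <- intersect(g_objs(g, f, IRI_RANGE), av_subclasses)
        opts <- if (length(rng)) g_typed(g, rng[1]) else character(0)
        if (!length(rng) || !length(opts)) {
          err("r6", f, paste0("choice field must range over an AllowedValues ",
                              "subclass with at least one option"))
        }
      }
      if (g_flag(g, f, MM("webIdProperty"))) id_fields <- c(id_fields, f)
    }
    if (length(id_fields) > 1L) {
      err("r11", d, paste0("multiple id fields declared: ",
                           paste(iri_local(id_fields), collapse = ", ")))
    }
  }
  for (m in parts$menu_props) {
    is_obj <- IRI_OBJPROP %in% g_types(g, m)
    dom <- intersect(g_objs(g, m, IRI_DOMAIN), ds)
    rng <- intersect(g_objs(g, m, IRI_RANGE), ds)
    if (!is_obj || !length(dom) || !length(rng)) {
      err("r4", m, paste0("menu entry must be an object property linking ",
                          "DataStructures"))
    }
  }
  for (av in av_subclasses) {
    coded <- MM("CodedValues") %in% c(av, g_supers(g, av))
    for (opt in g_typed(g, av)) {
      if (is.na(g_int(g, opt, MM("order")))) {
        err("r8", opt, "option lacks an order rank")
      }
      if (coded && is.na(g_lit(g, opt, MM("code")))) {
        err("r7", opt, "coded option lacks a code")
      }
    }
  }
  dd_props <- unique(g$df$subject[g$df$predicate == MM("webDirectlyDependent") &
                                    g$df$object %in% c("true", "1")])
  for (p in dd_props) {
    if (!(IRI_OBJPROP %in% g_types(g, p))) {
      err("r10", p, "webDirectlyDependent is only valid on object properties")
    }
  }
  errors <- if (length(errors)) do.call(rbind, errors) else
    data.frame(code = character(0), subject = character(0),
               message = character(0), stringsAsFactors = FALSE)
  warnings <- if (length(warnings)) do.call(rbind, warnings) else
    data.frame(code = character(0), subject = character(0),
               message = character(0), stringsAsFactors = FALSE)
  structure(list(errors = errors, warnings = warnings,
                 is_valid = nrow(errors) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", if (x$is_valid) "VALID" else "INVALID",
      ": ", nrow(x$errors), " errors, ", nrow(x$warnings), " warnings\n",
      sep = "")
  if (nrow(x$errors)) {
    for (i in seq_len(nrow(x$errors))) {
      cat("  [", x$errors$code[i], "] ", x$errors$message[i],
          if (!is.na(x$errors$subject[i]))
            paste0(" <", x$errors$subject[i], ">"), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Serialize a validation report as JSON
#' @param report A `validation_report`.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  jsonlite::toJSON(list(is_valid = report$is_valid,
                        errors = report$errors, warnings = report$warnings),
                   auto_unbox = TRUE, pretty = TRUE)
}

# ---- field specs -----------------------------------------------------------

#' Resolved field specifications of a form
#'
#' @param app A valid application [statement_set()].
#' @param data_structure The DataStructure class IRI.
#' @return A list of field specs ordered by (webRow, webColumn); each spec
#'   has the property IRI, widget kind, facets, the range, and (for choice
#'   fields) the resolved option list in rank order.
#' @export
field_specs <- function(app, data_structure) {
  g <- mm_graph(app)
  parts <- app_structures(g)
  if (!(data_structure %in% parts$ds)) {
    stop("unknown DataStructure: <", data_structure, ">")
  }
  fields <- parts$fields_of(data_structure)
  specs <- lapply(fields, function(f) field_spec_one(g, f))
  ord <- order(vapply(specs, function(s) s$facets$web_row, 1L),
               vapply(specs, function(s) s$facets$web_column, 1L))
  specs[ord]
}

field_spec_one <- function(g, f) {
  w <- field_widget(g, f)
  w <- if (length(w)) w[1] else NA_character_
  facets <- list(
    web_row = g_int(g, f, MM("webRow")),
    web_column = g_int(g, f, MM("webColumn")),
    is_description = g_flag(g, f, MM("webDescriptionProperty")),
    is_mandatory = g_flag(g, f, MM("webMandatoryProperty")) ||
      g_flag(g, f, MM("webIdProperty")),   # id fields are mandatory
    is_id = g_flag(g, f, MM("webIdProperty")),
    edition_disabled = g_flag(g, f, MM("webEditionDisabled")),
    directly_dependent = g_flag(g, f, MM("webDirectlyDependent")))
  rng <- g_objs(g, f, IRI_RANGE)
  av <- rng[vapply(rng, function(r)
    MM("AllowedValues") %in% g_supers(g, r), logical(1))]
  options <- NULL
  if (length(av)) {
    coded <- MM("CodedValues") %in% c(av[1], g_supers(g, av[1]))
    opts <- g_typed(g, av[1])
    if (length(opts)) {
      options <- data.frame(
        iri = opts,
        label = vapply(opts, function(o) {
          l <- g_lit(g, o, IRI_LABEL)
          if (is.na(l)) iri_local(o) else l
        }, character(1)),
        code = vapply(opts, function(o) g_lit(g, o, MM("code")), character(1)),
        rank = vapply(opts, function(o) g_int(g, o, MM("order")), integer(1)),
        stringsAsFactors = FALSE)
      options <- options[order(options$rank, options$iri), , drop = FALSE]
      rownames(options) <- NULL
      attr(options, "coded") <- coded
    }
  }
  is_obj <- IRI_OBJPROP %in% g_types(g, f)
  tag <- if (length(rng)) {
    t <- XSD_TO_TAG[rng[1]]
    if (is.na(t)) NA_character_ else unname(t)
  } else NA_character_
  list(property = f, local = iri_local(f), widget = w, facets = facets,
       range = if (length(rng)) rng[1] else NA_character_,
       value_tag = tag, is_object = is_obj, options = options)
}
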