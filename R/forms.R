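# Form-model compilation: turn a validated application ontology into the
# renderable description of its menus, forms, widgets, grid positions and
# value constraints.  This is the package's stand-in for a live portal: the
# model is built dynamically from the ontology and rendered as a
# schema-stable JSON bundle (optionally as static HTML for inspection).

#' Compile a validated application ontology into a form model
#'
#' @param app A valid application [statement_set()] (see
#'   [validate_application()]); invalid applications are refused with a
#'   pointer to the report.
#' @return A `form_model`: application IRI, case root, ordered menu, one
#'   field grid per DataStructure (SubForm fields are skipped), and the
#'   description columns per form.
#' @export
compile_forms <- function(app) {
  report <- validate_application(app)
  if (!report$is_valid) {
    stop("application is invalid (", nrow(report$errors),
         " errors); see validate_application() report, first error: [",
         report$errors$code[1], "] ", report$errors$message[1])
  }
  g <- mm_graph(app)
  parts <- app_structures(g)
  apps <- sort(g_typed(g, MM("Application")))
  menu_rows <- list()
  for (m in sort(parts$menu_props)) {
    lab <- g_lit(g, m, IRI_LABEL)
    if (is.na(lab)) lab <- iri_local(m)
    for (target in sort(intersect(g_objs(g, m, IRI_RANGE), parts$ds))) {
      menu_rows[[length(menu_rows) + 1L]] <-
        data.frame(label = lab, property = m, target = target,
                   stringsAsFactors = FALSE)
    }
  }
  menu <- if (length(menu_rows)) do.call(rbind, menu_rows) else
    data.frame(label = character(0), property = character(0),
               target = character(0), stringsAsFactors = FALSE)
  ranged <- unique(menu$target)
  roots <- setdiff(parts$ds, ranged)
  forms <- lapply(parts$ds, function(d) {
    specs <- field_specs(app, d)
    specs <- Filter(function(s) !identical(s$widget, "SubForm"), specs)
    list(data_structure = d, local = iri_local(d),
         reportable = MM("Reportable") %in% g_supers(g, d),
         fields = specs)
  })
  names(forms) <- parts$ds
  desc <- lapply(forms, function(f) {
    vapply(Filter(function(s) isTRUE(s$facets$is_description), f$fields),
           function(s) s$property, character(1))
  })
  structure(list(application = if (length(apps)) apps[1] else NA_character_,
                 case_root = if (length(roots)) sort(roots)[1] else
                   NA_character_,
                 menu = menu, forms = forms, description_columns = desc),
            class = "form_model")
}

#' @export
print.form_model <- function(x, ...) {
  cat("<form_model> application <", x$application, ">: ",
      length(x$forms), " forms, ", nrow(x$menu), " menu entries\n", sep = "")
  invisible(x)
}

#' Render a form model as a schema-stable JSON document
#'
#' The JSON layout is documented by the schema shipped in
#' `inst/schema/form-model.schema.json`; rendering the same model twice
#' yields byte-identical output.
#'
#' @param model A `form_model`.
#' @return A JSON string.
#' @export
render_form_model <- function(model) {
  field_json <- function(s) {
    list(property = s$property, local = s$local, widget = s$widget,
         row = s$facets$web_row, column = s$facets$web_column,
         facets = list(
           description = s$facets$is_description,
           mandatory = s$facets$is_mandatory,
           id = s$facets$is_id,
           edition_disabled = s$facets$edition_disabled,
           directly_dependent = s$facets$directly_dependent),
         range = s$range, value_tag = s$value_tag, is_object = s$is_object,
         options = if (is.null(s$options)) list() else
           lapply(seq_len(nrow(s$options)), function(i)
             list(iri = s$options$iri[i], label = s$options$label[i],
                  code = s$options$code[i], rank = s$options$rank[i])))
  }
  doc <- list(
    schema_version = "1.0",
    application = model$application,
    case_root = model$case_root,
    menu = lapply(seq_len(nrow(model$menu)), function(i)
      list(label = model$menu$label[i], property = model$menu$property[i],
           target = model$menu$target[i])),
    forms = lapply(model$forms[sort(names(model$forms))], function(f)
      list(data_structure = f$data_structure, local = f$local,
           reportable = f$reportable,
           description_columns =
             as.list(model$description_columns[[f$data_structure]]),
           fields = lapply(f$fields, field_json)))
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                                null = "null", na = "null"))
}

#' Parse a rendered form-model JSON document back into a form model
#'
#' @param json A string produced by [render_form_model()].
#' @return A `form_model` equal (up to re-rendering) to the original.
#' @export
parse_form_model <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  menu <- if (length(doc$menu)) do.call(rbind, lapply(doc$menu, function(m)
    data.frame(label = m$label, property = m$property, target = m$target,
               stringsAsFactors = FALSE))) else
    data.frame(label = character(0), property = character(0),
               target = character(0), stringsAsFactors = FALSE)
  forms <- lapply(doc$forms, function(f) {
    fields <- lapply(f$fields, function(s) {
      opts <- NULL
      if (length(s$options)) {
        opts <- do.call(rbind, lapply(s$options, function(o)
          data.frame(iri = o$iri, label = o$label,
                     code = if (is.null(o$code)) NA_character_ else o$code,
                     rank = o$rank, stringsAsFactors = FALSE)))
      }
      list(property = s$property, local = s$local, widget = s$widget,
           facets = list(web_row = s$row, web_column = s$column,
                         is_description = s$facets$description,
                         is_mandatory = s$facets$mandatory,
                         is_id = s$facets$id,
                         edition_disabled = s$facets$edition_disabled,
                         directly_dependent = s$facets$directly_dependent),
           range = if (is.null(s$range)) NA_character_ else s$range,
           value_tag = if (is.null(s$value_tag)) NA_character_ else
             s$value_tag,
           is_object = s$is_object, options = opts)
    })
    list(data_structure = f$data_structure, local = f$local,
         reportable = f$reportable, fields = fields)
  })
  names(forms) <- vapply(forms, function(f) f$data_structure, character(1))
  desc <- lapply(doc$forms, function(f)
    unlist(lapply(f$description_columns, identity)))
  desc <- lapply(desc, function(d) if (is.null(d)) character(0) else d)
  names(desc) <- names(forms)
  structure(list(application = doc$application, case_root = doc$case_root,
                 menu = menu, forms = forms, description_columns = desc),
            class = "form_model")
}

#' Render a form model as a static HTML page (human inspection only)
#'
#' @param model A `form_model`.
#' @return A single HTML string.
#' @export
render_form_html <- function(model) {
  esc <- xml_escape_text
  parts <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'/>",
             paste0("<title>", esc(iri_local(model$application)), "</title>"),
             "</head><body>",
             paste0("<h1>", esc(iri_local(model$application)), "</h1>"),
             "<ul class='menu'>")
  for (i in seq_len(nrow(model$menu))) {
    parts <- c(parts, paste0("<li><a href='#", esc(iri_local(model$menu$target[i])),
                             "'>", esc(model$menu$label[i]), "</a></li>"))
  }
  parts <- c(parts, "</ul>")
  for (f in model$forms[sort(names(model$forms))]) {
    parts <- c(parts, paste0("<h2 id='", esc(f$local), "'>", esc(f$local),
                             "</h2>"), "<table border='1'>")
    for (s in f$fields) {
      parts <- c(parts, paste0(
        "<tr><td>", s$facets$web_row, ",", s$facets$web_column, "</td><td>",
        esc(s$local), "</td><td>", esc(s$widget), "</td><td>",
        if (!is.null(s$options)) esc(paste(s$options$label, collapse = " | "))
        else "", "</td></tr>"))
    }
    parts <- c(parts, "</table>")
  }
  paste(c(parts, "</body></html>"), collapse = "\n")
}
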