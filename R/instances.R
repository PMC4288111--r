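# Constraint-enforcing instance CRUD.  Instance data are stored as ordinary
# statements under the application's data namespace (`<app IRI>/data`), so
# replacing the model ontology never touches collected data, and all facet
# constraints (mandatory, id uniqueness, option membership, value types,
# edition lock, dependent cascade) are enforced here.  Checks run in a fixed
# order -- mandatory, id uniqueness, options, types -- and any rejection
# leaves the repository unchanged.

data_namespace <- function(app_ns) paste0(app_ns, "/data")

reject <- function(code, ...) {
  msg <- paste0("[", code, "] ", paste0(...))
  cond <- structure(class = c("ontoreg_reject", "error", "condition"),
                    list(message = msg, call = NULL, code = code))
  stop(cond)
}

#' Rejection code of a condition
#' @param e A condition raised by the CRUD layer.
#' @return The rejection code string, or `NA`.
#' @export
reject_code <- function(e) {
  if (!is.null(e$code)) e$code else NA_character_
}

# Compiled field specs for a DataStructure, cached per repository and
# invalidated whenever an ontology is (bulk) loaded.
form_specs_for <- function(repo, ds_id) {
  key <- as.character(ds_id)
  if (is.null(repo$form_cache)) repo$form_cache <- new.env(parent = emptyenv())
  hit <- get0(key, envir = repo$form_cache, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  ns <- gtab_get(repo$tables$resources, "ontology_ns", ds_id)
  app <- download_ontology(repo, ns)
  specs <- field_specs(app, res_iri_of(repo, ds_id))
  menu_props <- g_typed(mm_graph(app), MM("MenuItem"))
  out <- list(ns = ns, specs = specs, menu_props = menu_props)
  assign(key, out, envir = repo$form_cache)
  out
}

clear_form_cache <- function(repo) {
  repo$form_cache <- new.env(parent = emptyenv())
}

# Normalize user-supplied values: names may be property IRIs or local names.
match_values <- function(specs, values) {
  if (is.null(values)) values <- list()
  by_iri <- stats::setNames(seq_along(specs),
                            vapply(specs, function(s) s$property, character(1)))
  by_local <- stats::setNames(seq_along(specs),
                              vapply(specs, function(s) s$local, character(1)))
  out <- stats::setNames(vector("list", length(specs)), names(by_iri))
  provided <- logical(length(specs))
  for (nm in names(values)) {
    i <- if (nm %in% names(by_iri)) by_iri[[nm]]
      else if (nm %in% names(by_local)) by_local[[nm]]
      else reject("UNKNOWN_FIELD", "no such field: ", nm)
    out[[i]] <- values[[nm]]
    provided[i] <- TRUE
  }
  list(values = out, provided = provided)
}

resolve_option <- function(spec, v) {
  o <- spec$options
  if (is.null(o)) return(NA_character_)
  hit <- which(o$iri == v | o$label == v |
                 (!is.na(o$code) & o$code == v))
  if (length(hit)) o$iri[hit[1]] else NA_character_
}

id_value_exists <- function(repo, ds_id, spec, v) {
  pid <- res_lookup(repo, spec$property)
  if (is.na(pid)) return(FALSE)
  live <- instances_of(repo, ds_id)
  tag <- if (!is.na(spec$value_tag)) spec$value_tag else "string"
  tab <- gtab_dt(repo$tables[[paste0("value_", tag)]])
  tab <- tab[!tab$deleted & tab$property_id == pid]
  any(tab$instance_id %in% live &
        tab$lex == lexical_canon(as.character(v), tag))
}

# The shared constraint gate; returns the validated (iri-keyed) value list.
check_values <- function(repo, ds_id, specs, mv, require_mandatory = TRUE,
                         skip_instance = NA_integer_) {
  values <- mv$values; provided <- mv$provided
  # 1. mandatory
  if (require_mandatory) {
    for (i in seq_along(specs)) {
      s <- specs[[i]]
      if (!isTRUE(s$facets$is_mandatory)) next
      if (identical(s$widget, "LiteralProperty")) next
      if (field_deprecated(repo, s)) next
      v <- values[[i]]
      if (is.null(v) || !length(v) || all(is.na(v)) ||
          all(!nzchar(as.character(v)))) {
        reject("MANDATORY_MISSING", "mandatory field not filled: ", s$local)
      }
    }
  }
  # 2. id uniqueness
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (!isTRUE(s$facets$is_id) || !provided[i]) next
    v <- values[[i]]
    if (is.null(v)) next
    if (!is.na(skip_instance)) {
      cur <- values_of(repo, skip_instance, s$property)
      if (nrow(cur) && any(cur$lex == as.character(v), na.rm = TRUE)) next
    }
    if (id_value_exists(repo, ds_id, s, v)) {
      reject("ID_NOT_UNIQUE", "id value already in use: ", as.character(v))
    }
  }
  # 3. option membership
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (!provided[i] || is.null(s$options)) next
    v <- values[[i]]
    if (is.null(v)) next
    resolved <- vapply(as.character(v), function(x) resolve_option(s, x),
                       character(1))
    if (anyNA(resolved)) {
      reject("OPTION_INVALID", "value not among the allowed options of ",
             s$local, ": ", paste(v[is.na(resolved)], collapse = ", "))
    }
    values[[i]] <- unname(resolved)
  }
  # 4. value types
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (!provided[i] || !is.null(s$options)) next
    v <- values[[i]]
    if (is.null(v)) next
    if (s$is_object) {
      for (x in as.character(v)) {
        oid <- res_lookup(repo, x)
        ok <- !is.na(oid) && !gtab_get(repo$tables$resources, "deleted", oid)
        if (!ok) reject("TYPE_MISMATCH", "object value of ", s$local,
                        " is not a live resource: ", x)
      }
    } else {
      tag <- if (!is.na(s$value_tag)) s$value_tag else "string"
      bad <- !lexical_ok(as.character(v), tag)
      if (any(bad)) {
        reject("TYPE_MISMATCH", "value of ", s$local, " is not a valid ",
               tag, ": ", paste(as.character(v)[bad], collapse = ", "))
      }
    }
  }
  values
}

field_deprecated <- function(repo, spec) {
  pid <- res_lookup(repo, spec$property)
  !is.na(pid) && is_deprecated(repo, pid)
}

#' Create an instance of a DataStructure
#'
#' Checks run in order: mandatory fields present, id-field uniqueness among
#' live instances, option membership for constrained fields, value types
#' against declared ranges.  On success the typed value rows are written
#' (through the statements table) and, when the DataStructure is a subclass
#' of Reportable, exactly one creation notification is emitted.
#'
#' @param repo An `ontoreg_repo`.
#' @param data_structure DataStructure IRI (or id).
#' @param values Named list; names are field IRIs or local names, values are
#'   scalars or vectors (multi-valued object fields).
#' @return The new instance's resource id, invisibly.
#' @export
create_instance <- function(repo, data_structure, values = list()) {
  ds_id <- res_resolve(repo, data_structure)
  if (is_deprecated(repo, ds_id)) {
    reject("DEPRECATED", "DataStructure is deprecated; no new instances: ",
           res_iri_of(repo, ds_id))
  }
  fs <- form_specs_for(repo, ds_id)
  mv <- match_values(fs$specs, values)
  vals <- check_values(repo, ds_id, fs$specs, mv)
  ds_iri <- res_iri_of(repo, ds_id)
  dns <- data_namespace(fs$ns)
  inst_iri <- paste0(dns, "#", iri_local(ds_iri), "_",
                     gtab_n(repo$tables$resources) + 1L)
  assert_statement(repo, stmt(inst_iri, IRI_TYPE, ds_iri), ns = dns)
  inst_id <- res_lookup(repo, inst_iri)
  write_field_values(repo, inst_iri, fs$specs, vals, mv$provided, dns)
  reportable <- res_lookup(repo, MM("Reportable"))
  if (!is.na(reportable) &&
      reportable %in% superclasses_of(repo, ds_id, transitive = TRUE)) {
    notif <- structure(list(data_structure = ds_iri, instance_id = inst_id,
                            timestamp = Sys.time(), recipients = character(0)),
                       class = "ontoreg_notification")
    repo$notifications[[length(repo$notifications) + 1L]] <- notif
    if (is.function(repo$notify_hook)) repo$notify_hook(notif)
  }
  invisible(inst_id)
}

write_field_values <- function(repo, inst_iri, specs, vals, provided, dns) {
  for (i in seq_along(specs)) {
    if (!provided[i]) next
    s <- specs[[i]]
    v <- vals[[i]]
    if (is.null(v) || !length(v)) next
    for (x in v) {
      if (s$is_object || !is.null(s$options)) {
        assert_statement(repo, stmt(inst_iri, s$property, as.character(x),
                                    "iri"), ns = dns)
      } else {
        tag <- if (!is.na(s$value_tag)) s$value_tag else "string"
        assert_statement(repo, lit_stmt(inst_iri, s$property,
                                        as.character(x), tag), ns = dns)
      }
    }
  }
}

#' Update a live instance
#'
#' Same constraint gate as [create_instance()]; id uniqueness is re-checked
#' only when the id field changes, and edits to edition-disabled or
#' deprecated fields are rejected.
#'
#' @param repo An `ontoreg_repo`.
#' @param instance Instance id (or IRI).
#' @param values Named list of fields to change.
#' @return Summary list (instance id, number of value rows changed),
#'   invisibly.
#' @export
update_instance <- function(repo, instance, values = list()) {
  inst_id <- tryCatch(res_resolve(repo, instance),
                      error = function(e) reject("UNKNOWN_INSTANCE",
                                                 conditionMessage(e)))
  ds_id <- instance_class_of(repo, inst_id)
  fs <- form_specs_for(repo, ds_id)
  mv <- match_values(fs$specs, values)
  # edition lock + deprecation: reject attempts to change locked fields
  for (i in seq_along(fs$specs)) {
    s <- fs$specs[[i]]
    if (!mv$provided[i]) next
    locked <- isTRUE(s$facets$edition_disabled) || field_deprecated(repo, s)
    if (!locked) next
    cur <- values_of(repo, inst_id, s$property)
    curv <- c(cur$lex[!is.na(cur$lex)], cur$object[!is.na(cur$object)])
    newv <- as.character(unlist(mv$values[[i]]))
    if (!setequal(curv, newv)) {
      reject(if (isTRUE(s$facets$edition_disabled)) "EDITION_DISABLED"
             else "DEPRECATED",
             "field cannot be edited: ", s$local)
    }
  }
  vals <- check_values(repo, ds_id, fs$specs, mv, require_mandatory = FALSE,
                       skip_instance = inst_id)
  # mandatory fields cannot be blanked
  for (i in seq_along(fs$specs)) {
    s <- fs$specs[[i]]
    if (mv$provided[i] && isTRUE(s$facets$is_mandatory)) {
      v <- vals[[i]]
      if (is.null(v) || !length(v) || all(!nzchar(as.character(v)))) {
        reject("MANDATORY_MISSING", "mandatory field cannot be cleared: ",
               s$local)
      }
    }
  }
  inst_iri <- res_iri_of(repo, inst_id)
  dns <- data_namespace(fs$ns)
  changed <- 0L
  for (i in seq_along(fs$specs)) {
    if (!mv$provided[i]) next
    s <- fs$specs[[i]]
    cur <- values_of(repo, inst_id, s$property)
    curv <- c(cur$lex[!is.na(cur$lex)], cur$object[!is.na(cur$object)])
    newv <- as.character(unlist(vals[[i]]))
    if (setequal(curv, newv)) next
    # retract current, assert new
    for (j in seq_len(nrow(cur))) {
      st <- if (!is.na(cur$object[j])) {
        stmt(inst_iri, s$property, cur$object[j], "iri")
      } else {
        lit_stmt(inst_iri, s$property, cur$lex[j], cur$tag[j])
      }
      retract_statement(repo, st)
      changed <- changed + 1L
    }
    write_field_values(repo, inst_iri, fs$specs[i], vals[i], TRUE, dns)
    changed <- changed + length(newv)
  }
  invisible(list(instance_id = inst_id, rows_changed = changed))
}

instance_class_of <- function(repo, inst_id) {
  io <- gtab_dt(repo$tables$instance_of)
  io <- io[!io$deleted & io$instance_id == inst_id]
  ds <- io$class_id[vapply(io$class_id, function(c)
    !is.null(get0(as.character(c), envir = repo$class_row)), logical(1))]
  if (!length(ds)) stop("not an instance of any class: ",
                        res_iri_of(repo, inst_id))
  ds[1]
}

# Properties flagged webDirectlyDependent = true (owner -> dependent links).
directly_dependent_props <- function(repo) {
  fid <- res_lookup(repo, MM("webDirectlyDependent"))
  if (is.na(fid)) return(integer(0))
  tab <- gtab_dt(repo$tables$value_boolean)
  tab <- tab[!tab$deleted & tab$property_id == fid & tab$lex == "true"]
  unique(tab$instance_id)   # the flagged properties (punned as subjects)
}

#' Soft-delete an instance with dependent cascade
#'
#' The instance is flagged deleted, along with every instance reachable over
#' directly-dependent properties (values that cannot exist without their
#' owner), recursively.  All physical rows are retained.
#'
#' @param repo An `ontoreg_repo`.
#' @param instance Instance id (or IRI); must be live.
#' @return Integer vector of all flagged instance ids, invisibly.
#' @export
delete_instance <- function(repo, instance) {
  inst_id <- res_resolve(repo, instance)   # errors on unknown/deleted
  dd <- directly_dependent_props(repo)
  vr <- gtab_dt(repo$tables$value_resource)
  vr <- vr[!vr$deleted]
  res_deleted <- gtab_get(repo$tables$resources, "deleted",
                          seq_len(gtab_n(repo$tables$resources)))
  # transitive reachability over dependent links, computed up front
  flagged <- integer(0); queue <- inst_id
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur %in% flagged) next
    flagged <- c(flagged, cur)
    deps <- vr$object_id[vr$instance_id == cur & vr$property_id %in% dd]
    deps <- deps[!res_deleted[deps]]
    queue <- c(queue, setdiff(deps, flagged))
  }
  eff_env <- new.env(parent = emptyenv()); eff_env$eff <- new_effect()
  st <- repo$tables$statements
  for (id in flagged) {
    n <- gtab_n(st)
    subj <- gtab_get(st, "subject_id", seq_len(n))
    del <- gtab_get(st, "deleted", seq_len(n))
    for (sid in which(subj == id & !del)) do_retract(repo, sid, eff_env)
    gtab_set(repo$tables$resources, "deleted", id, TRUE)
  }
  invisible(sort(flagged))
}

#' List the live instances of a DataStructure
#'
#' @param repo An `ontoreg_repo`.
#' @param data_structure DataStructure IRI (or id).
#' @return A data.frame with `instance_id`, `instance` (IRI), and one column
#'   per description-flagged field, in (row, column) order.
#' @export
list_instances <- function(repo, data_structure) {
  ds_id <- res_resolve(repo, data_structure)
  fs <- form_specs_for(repo, ds_id)
  desc <- Filter(function(s) isTRUE(s$facets$is_description), fs$specs)
  ids <- instances_of(repo, ds_id)
  out <- data.frame(instance_id = ids,
                    instance = if (length(ids)) res_iri_of(repo, ids)
                               else character(0),
                    stringsAsFactors = FALSE)
  for (s in desc) {
    col <- vapply(ids, function(i) {
      v <- values_of(repo, i, s$property)
      if (!nrow(v)) return(NA_character_)
      shown <- ifelse(is.na(v$lex), option_label(s, v$object), v$lex)
      paste(shown, collapse = "; ")
    }, character(1))
    out[[s$local]] <- col
  }
  out
}

option_label <- function(spec, iris) {
  if (is.null(spec$options)) return(iris)
  lab <- spec$options$label[match(iris, spec$options$iri)]
  ifelse(is.na(lab), iris, lab)
}

#' Register a notification hook
#'
#' The hook is called once per creation of an instance of a Reportable
#' DataStructure (delivery, e.g. email, is the host system's business).
#'
#' @param repo An `ontoreg_repo`.
#' @param hook `function(notification)` or `NULL` to unregister.
#' @return The repository, invisibly.
#' @export
set_notify_hook <- function(repo, hook) {
  repo$notify_hook <- hook
  invisible(repo)
}

#' Notifications emitted so far
#' @param repo An `ontoreg_repo`.
#' @return List of `ontoreg_notification` records.
#' @export
notifications <- function(repo) repo$notifications

#' Whole-repository constraint audit
#'
#' An independent pass (separate from the create/update gate) that walks the
#' raw value tables and re-checks every facet constraint for every live
#' instance of every DataStructure of an application: mandatory fields
#' filled, id values unique, constrained values among the options, typed
#' values in the table matching the declared range.
#'
#' @param repo An `ontoreg_repo`.
#' @param app_ns Application (model) namespace.
#' @return A data.frame of violations (empty when the repository is sound).
#' @export
audit_repository <- function(repo, app_ns) {
  app <- download_ontology(repo, app_ns)
  g <- mm_graph(app)
  parts <- app_structures(g)
  bad <- list()
  note <- function(instance, field, what) {
    bad[[length(bad) + 1L]] <<- data.frame(instance = instance, field = field,
                                           violation = what,
                                           stringsAsFactors = FALSE)
  }
  for (d in parts$ds) {
    ds_id <- res_lookup(repo, d)
    if (is.na(ds_id)) next
    specs <- field_specs(app, d)
    ids <- instances_of(repo, ds_id)
    id_seen <- character(0)
    for (i in ids) {
      vals <- values_of(repo, i)
      for (s in specs) {
        v <- vals[vals$property == s$property, , drop = FALSE]
        if (isTRUE(s$facets$is_mandatory) &&
            !identical(s$widget, "LiteralProperty") &&
            !field_deprecated(repo, s) && !nrow(v)) {
          note(i, s$local, "mandatory field empty")
        }
        if (isTRUE(s$facets$is_id) && nrow(v)) {
          key <- paste0(s$property, "=", v$lex[1])
          if (key %in% id_seen) note(i, s$local, "duplicate id value")
          id_seen <- c(id_seen, key)
        }
        if (!is.null(s$options) && nrow(v)) {
          out_of_set <- setdiff(v$object[!is.na(v$object)], s$options$iri)
          if (length(out_of_set)) note(i, s$local, "value outside option list")
        }
        if (is.null(s$options) && !s$is_object && nrow(v) &&
            !is.na(s$value_tag)) {
          if (any(v$tag[!is.na(v$lex)] != s$value_tag)) {
            note(i, s$local, "value hosted in wrong range table")
          }
        }
      }
    }
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(instance = integer(0), field = character(0),
               violation = character(0), stringsAsFactors = FALSE)
}
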