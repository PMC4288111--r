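# Statement propagation.  Adding or retracting a statement in the statements
# table updates the structural tables (resource kinds, class/property rows,
# domain/range rows, subsumption edges, instance-of rows, typed value rows)
# so that at any point the structural state equals what a from-scratch
# rebuild from the live statements would produce.  The paper's triggers are
# realized as transactional application-level propagation with the same
# observable semantics.

new_effect <- function() {
  structure(list(inserted = integer(0), flagged = integer(0),
                 warnings = character(0)), class = "propagation_effect")
}

eff_add <- function(eff, what, table, n = 1L) {
  cur <- eff[[what]]
  cur[table] <- (if (table %in% names(cur)) cur[[table]] else 0L) + n
  eff[[what]] <- cur
  eff
}

#' @export
print.propagation_effect <- function(x, ...) {
  ins <- sum(x$inserted); flg <- sum(x$flagged)
  cat("<propagation_effect> ", ins, " rows inserted, ", flg,
      " rows flagged", if (length(x$warnings))
        paste0(", ", length(x$warnings), " warnings"), "\n", sep = "")
  invisible(x)
}

# Explicit metatype conferred by the live rdf:type objects of a resource.
explicit_metatype <- function(repo, rid) {
  tvec <- vec_get(repo$types_of, rid)
  if (!length(tvec)) return(NA_character_)
  mt <- METATYPE_MAP[res_iri_of(repo, tvec)]
  mt <- unique(mt[!is.na(mt)])
  if (!length(mt)) NA_character_ else mt
}

cls_like_rid <- function(repo, rid) {
  iri <- res_iri_of(repo, rid)
  if (!is.na(builtin_kinds(iri))) return(FALSE)  # builtins handled separately
  mt <- explicit_metatype(repo, rid)
  if (isTRUE(mt[1] == "class")) return(TRUE)
  length(vec_get(repo$type_subj_of, rid)) > 0L
}

derive_kind <- function(repo, rid) {
  iri <- res_iri_of(repo, rid)
  bk <- builtin_kinds(iri)
  if (!is.na(bk)) return(bk)
  mt <- explicit_metatype(repo, rid)
  mt <- if (length(mt)) mt[1] else NA_character_
  if (!is.na(mt) && mt != "class") return(mt)
  if (cls_like_rid(repo, rid)) {
    return(if (get_count(repo$cls_inst_count, rid) > 0L) "metaclass"
           else "named_class")
  }
  if (get_count(repo$pred_count, rid) > 0L) return("annotation_property")
  "individual"
}

# Recompute and store the kind of a resource; keep class/property role tables
# in step.  Returns the new kind.
update_kind <- function(repo, rid, eff_env = NULL) {
  k <- derive_kind(repo, rid)
  res <- repo$tables$resources
  old <- gtab_get(res, "kind", rid)
  if (!identical(old, k)) gtab_set(res, "kind", rid, k)
  sync_role_row(repo, rid, "classes", "class_row", k %in% CLASS_KINDS, eff_env)
  sync_role_row(repo, rid, "properties", "prop_row", k %in% PROPERTY_KINDS,
                eff_env)
  k
}

sync_role_row <- function(repo, rid, tabname, mapname, should_live, eff_env) {
  row <- get0(as.character(rid), envir = repo[[mapname]], ifnotfound = NA)
  tab <- repo$tables[[tabname]]
  if (should_live) {
    if (is.na(row)) {
      i <- gtab_add(tab, list(resource_id = rid, deleted = FALSE))
      assign(as.character(rid), i, envir = repo[[mapname]])
      if (!is.null(eff_env)) eff_env$eff <- eff_add(eff_env$eff, "inserted", tabname)
    } else if (gtab_get(tab, "deleted", row)) {
      gtab_set(tab, "deleted", row, FALSE)
      if (!is.null(eff_env)) eff_env$eff <- eff_add(eff_env$eff, "inserted", tabname)
    }
  } else if (!is.na(row) && !gtab_get(tab, "deleted", row)) {
    gtab_set(tab, "deleted", row, TRUE)
    if (!is.null(eff_env)) eff_env$eff <- eff_add(eff_env$eff, "flagged", tabname)
  }
}

# Get-or-create a resource row; ids are monotone and never reused.
res_ensure <- function(repo, iri, ns, eff_env = NULL) {
  id <- res_lookup(repo, iri)
  if (!is.na(id)) return(id)
  res <- repo$tables$resources
  id <- gtab_n(res) + 1L
  gtab_add(res, list(id = id, iri = iri, kind = "individual",
                     ontology_ns = ns, deprecated = FALSE, deleted = FALSE))
  assign(iri, id, envir = repo$res_id)
  if (!is.null(eff_env)) eff_env$eff <- eff_add(eff_env$eff, "inserted", "resources")
  bk <- builtin_kinds(iri)
  if (!is.na(bk)) update_kind(repo, id, eff_env)
  id
}

# Declared range tag of a property: among its live ranges, the XSD datatype
# with the smallest resource id wins; NULL when no datatype range is declared.
refresh_range_tag <- function(repo, pid) {
  rg <- repo$tables$ranges
  n <- gtab_n(rg)
  key <- as.character(pid)
  if (n) {
    sel <- which(gtab_get(rg, "property_id", seq_len(n)) == pid &
                   !gtab_get(rg, "deleted", seq_len(n)))
    if (length(sel)) {
      rids <- sort(gtab_get(rg, "range_id", sel))
      for (rid in rids) {
        tag <- XSD_TO_TAG[res_iri_of(repo, rid)]
        if (!is.na(tag)) {
          assign(key, unname(tag), envir = repo$range_tag)
          return(unname(tag))
        }
      }
    }
  }
  if (exists(key, envir = repo$range_tag)) rm(list = key,
                                             envir = repo$range_tag)
  NULL
}

range_tag_of <- function(repo, pid) {
  get0(as.character(pid), envir = repo$range_tag, ifnotfound = NULL)
}

# Host tag for a literal value of property pid: declared range tag when the
# lexical form converts, else the string table (permissive fallback used
# identically by the incremental path and the rebuild).
host_tag <- function(repo, pid, lex) {
  declared <- range_tag_of(repo, pid)
  if (is.null(declared)) return(list(tag = "string", undeclared = TRUE))
  if (lexical_ok(lex, declared)) list(tag = declared, undeclared = FALSE)
  else list(tag = "string", undeclared = FALSE)
}

insert_value_row <- function(repo, tabname, inst, pid, lex_or_oid, stmt_id,
                             eff_env) {
  tab <- repo$tables[[tabname]]
  row <- if (tabname == "value_resource") {
    gtab_add(tab, list(instance_id = inst, property_id = pid,
                       object_id = lex_or_oid, stmt_id = stmt_id,
                       deleted = FALSE))
  } else {
    gtab_add(tab, list(instance_id = inst, property_id = pid,
                       lex = lex_or_oid, stmt_id = stmt_id, deleted = FALSE))
  }
  assign(as.character(stmt_id), list(tabname, row), envir = repo$val_row)
  if (tabname == "value_resource") vec_push(repo$objval_stmts, pid, stmt_id)
  else vec_push(repo$val_stmts, pid, stmt_id)
  if (!is.null(eff_env)) eff_env$eff <- eff_add(eff_env$eff, "inserted", tabname)
  row
}

flag_value_row <- function(repo, stmt_id, eff_env) {
  key <- as.character(stmt_id)
  ref <- get0(key, envir = repo$val_row, ifnotfound = NULL)
  if (is.null(ref)) return(invisible(NULL))
  tab <- repo$tables[[ref[[1]]]]
  gtab_set(tab, "deleted", ref[[2]], TRUE)
  pid <- gtab_get(tab, "property_id", ref[[2]])
  if (ref[[1]] == "value_resource") vec_drop(repo$objval_stmts, pid, stmt_id)
  else vec_drop(repo$val_stmts, pid, stmt_id)
  rm(list = key, envir = repo$val_row)
  if (!is.null(eff_env)) eff_env$eff <- eff_add(eff_env$eff, "flagged", ref[[1]])
  invisible(NULL)
}

# Re-place live literal value rows of a property after its declared range
# changed (keeps propagation order-independent).
migrate_values <- function(repo, pid, eff_env) {
  stmts <- vec_get(repo$val_stmts, pid)
  if (!length(stmts)) return(invisible(NULL))
  st <- repo$tables$statements
  for (sid in stmts) {
    ref <- get0(as.character(sid), envir = repo$val_row, ifnotfound = NULL)
    if (is.null(ref)) next
    lex <- gtab_get(st, "object_lex", sid)
    ht <- host_tag(repo, pid, lex)
    target <- paste0("value_", ht$tag)
    if (identical(target, ref[[1]])) next
    inst <- gtab_get(repo$tables[[ref[[1]]]], "instance_id", ref[[2]])
    gtab_set(repo$tables[[ref[[1]]]], "deleted", ref[[2]], TRUE)
    if (!is.null(eff_env)) eff_env$eff <- eff_add(eff_env$eff, "flagged", ref[[1]])
    vec_drop(repo$val_stmts, pid, sid)
    insert_value_row(repo, target, inst, pid,
                     lexical_canon(lex, ht$tag), sid, eff_env)
  }
  invisible(NULL)
}

# Kind bookkeeping shared by assert and retract of rdf:type statements.
# `delta` is +1 (assert) or -1 (retract); called AFTER types_of/type_subj_of
# were updated.
type_kind_updates <- function(repo, sid, oid, cls_before_s, cls_before_o,
                              eff_env) {
  for (who in list(c(sid, cls_before_s), c(oid, cls_before_o))) {
    rid <- who[1]; before <- as.logical(who[2])
    now <- cls_like_rid(repo, rid)
    if (now != before) {
      # adjust class-instance counters of every class this resource is
      # currently typed by, then refresh their kinds
      for (C in vec_get(repo$types_of, rid)) {
        inc_count(repo$cls_inst_count, C, if (now) 1L else -1L)
        update_kind(repo, C, eff_env)
      }
    }
  }
  update_kind(repo, sid, eff_env)
  update_kind(repo, oid, eff_env)
}

#' Assert one statement into the repository
#'
#' The statement lands in the statements table and all structural tables are
#' propagated.  Duplicate asserts are idempotent (zero-effect); contradictory
#' typing (e.g. typing a known class as a datatype property) is rejected with
#' the statements table unchanged.
#'
#' @param repo An `ontoreg_repo`.
#' @param st A one-row statement (from [stmt()]).
#' @param ns Owning ontology namespace recorded on the statement row.
#' @return A `propagation_effect` summary, invisibly.
#' @export
assert_statement <- function(repo, st, ns = "urn:ontoreg:adhoc") {
  eff_env <- new.env(parent = emptyenv()); eff_env$eff <- new_effect()
  if (st$obj_kind == "literal" && !(st$lit_type %in% DATATYPE_TAGS)) {
    stop("unsupported literal datatype tag: ", st$lit_type)
  }
  # contradiction guard before anything is written
  if (st$predicate == IRI_TYPE && st$obj_kind != "literal") {
    new_mt <- unname(METATYPE_MAP[st$object])
    if (!is.na(new_mt)) {
      sid0 <- res_lookup(repo, st$subject)
      if (!is.na(sid0)) {
        cur <- explicit_metatype(repo, sid0)
        cur <- cur[!is.na(cur)]
        if (length(cur) && !all(cur == new_mt)) {
          stop("contradictory resource typing for <", st$subject, ">: already ",
               paste(cur, collapse = "/"), ", cannot also be ", new_mt)
        }
      }
    }
  }
  sid <- res_ensure(repo, st$subject, ns, eff_env)
  pid <- res_ensure(repo, st$predicate, ns, eff_env)
  oid <- if (st$obj_kind != "literal") res_ensure(repo, st$object, ns, eff_env)
         else NA_integer_
  key <- stmt_keys(sid, pid, oid, st$lit_type, st$object)
  if (!is.na(get0(key, envir = repo$stmt_key, ifnotfound = NA_integer_))) {
    return(invisible(eff_env$eff))   # duplicate: zero effect on live content
  }
  stab <- repo$tables$statements
  stmt_id <- gtab_n(stab) + 1L
  gtab_add(stab, list(
    id = stmt_id, subject_id = sid, predicate_id = pid,
    object_id = oid, object_lex = if (st$obj_kind == "literal") st$object
                                  else NA_character_,
    obj_kind = if (st$obj_kind == "literal") "literal" else "resource",
    lit_type = st$lit_type, ontology_ns = ns, deleted = FALSE))
  assign(key, stmt_id, envir = repo$stmt_key)
  eff_env$eff <- eff_add(eff_env$eff, "inserted", "statements")
  old_pred_count <- inc_count(repo$pred_count, pid, 1L) - 1L
  if (old_pred_count == 0L) update_kind(repo, pid, eff_env)

  pred <- st$predicate
  if (pred == IRI_TYPE && st$obj_kind != "literal") {
    cls_before_s <- cls_like_rid(repo, sid)
    cls_before_o <- cls_like_rid(repo, oid)
    vec_push(repo$types_of, sid, oid)
    vec_push(repo$type_subj_of, oid, sid)
    if (cls_before_s) inc_count(repo$cls_inst_count, oid, 1L)
    type_kind_updates(repo, sid, oid, cls_before_s, cls_before_o, eff_env)
    if (is.na(builtin_kinds(st$object))) {
      set_pair_row(repo, "instance_of", "inst_row",
                   list(instance_id = sid, class_id = oid, stmt_id = stmt_id,
                        deleted = FALSE),
                   paste0(sid, "|", oid), TRUE, eff_env)
    }
    repo$hier_stale <- TRUE
  } else if (pred == IRI_SUBCLASS && st$obj_kind != "literal") {
    set_pair_row(repo, "subclass_edges", "sub_row",
                 list(child_id = sid, parent_id = oid, stmt_id = stmt_id,
                      deleted = FALSE), paste0(sid, "|", oid), TRUE, eff_env)
    repo$hier_stale <- TRUE
  } else if (pred == IRI_SUBPROP && st$obj_kind != "literal") {
    set_pair_row(repo, "subprop_edges", "subp_row",
                 list(child_id = sid, parent_id = oid, stmt_id = stmt_id,
                      deleted = FALSE), paste0(sid, "|", oid), TRUE, eff_env)
    repo$hier_stale <- TRUE
  } else if (pred == IRI_DOMAIN && st$obj_kind != "literal") {
    set_pair_row(repo, "domains", "dom_row",
                 list(property_id = sid, class_id = oid, stmt_id = stmt_id,
                      deleted = FALSE), paste0(sid, "|", oid), TRUE, eff_env)
  } else if (pred == IRI_RANGE && st$obj_kind != "literal") {
    set_pair_row(repo, "ranges", "rng_row",
                 list(property_id = sid, range_id = oid, stmt_id = stmt_id,
                      deleted = FALSE), paste0(sid, "|", oid), TRUE, eff_env)
    refresh_range_tag(repo, sid)
    migrate_values(repo, sid, eff_env)
  } else if (pred == IRI_IMPORTS && st$obj_kind != "literal") {
    set_pair_row(repo, "imports_t", "imp_row",
                 list(importer_iri = st$subject, imported_iri = st$object,
                      stmt_id = stmt_id, deleted = FALSE),
                 paste0(st$subject, "|", st$object), TRUE, eff_env)
  } else if (st$obj_kind == "literal") {
    ht <- host_tag(repo, pid, st$object)
    if (ht$undeclared) {
      eff_env$eff$warnings <- c(eff_env$eff$warnings,
        paste0("property <", st$predicate,
               "> has no declared range; value stored as string"))
    }
    insert_value_row(repo, paste0("value_", ht$tag), sid, pid,
                     lexical_canon(st$object, ht$tag), stmt_id, eff_env)
  } else {
    insert_value_row(repo, "value_resource", sid, pid, oid, stmt_id, eff_env)
  }
  invisible(eff_env$eff)
}

# Insert-or-revive a keyed structural row.
set_pair_row <- function(repo, tabname, mapname, vals, key, live, eff_env) {
  row <- get0(key, envir = repo[[mapname]], ifnotfound = NA)
  tab <- repo$tables[[tabname]]
  if (is.na(row)) {
    if (!live) return(invisible(NULL))
    i <- gtab_add(tab, vals)
    assign(key, i, envir = repo[[mapname]])
    eff_env$eff <- eff_add(eff_env$eff, "inserted", tabname)
  } else {
    was_deleted <- gtab_get(tab, "deleted", row)
    if (live && was_deleted) {
      gtab_set(tab, "deleted", row, FALSE)
      gtab_set(tab, "stmt_id", row, vals$stmt_id)
      eff_env$eff <- eff_add(eff_env$eff, "inserted", tabname)
    } else if (!live && !was_deleted) {
      gtab_set(tab, "deleted", row, TRUE)
      eff_env$eff <- eff_add(eff_env$eff, "flagged", tabname)
    }
  }
  invisible(NULL)
}

#' Retract one statement (soft delete)
#'
#' The statement and its dependent structural rows are flagged deleted;
#' nothing is physically removed.  Retracting the class typing of a class
#' with live instances, or the property typing of a property with live
#' values, is refused to keep the repository consistent.
#'
#' @inheritParams assert_statement
#' @return A `propagation_effect`, invisibly.
#' @export
retract_statement <- function(repo, st, ns = NULL) {
  sid <- res_lookup(repo, st$subject)
  pid <- res_lookup(repo, st$predicate)
  oid <- if (st$obj_kind != "literal") res_lookup(repo, st$object)
         else NA_integer_
  if (is.na(sid) || is.na(pid) ||
      (st$obj_kind != "literal" && is.na(oid))) {
    stop("statement not present (unknown resource)")
  }
  key <- stmt_keys(sid, pid, oid, st$lit_type, st$object)
  stmt_id <- get0(key, envir = repo$stmt_key, ifnotfound = NA_integer_)
  if (is.na(stmt_id)) stop("statement not present")
  # consistency guards
  if (st$predicate == IRI_TYPE &&
      st$object %in% c(IRI_CLASS, IRI_RDFSCLASS)) {
    if (length(vec_get(repo$type_subj_of, sid))) {
      stop("cannot retract class typing of <", st$subject,
           ">: the class has live instances")
    }
  }
  if (st$predicate == IRI_TYPE &&
      st$object %in% c(IRI_DTPROP, IRI_OBJPROP, IRI_ANNPROP)) {
    if (length(vec_get(repo$val_stmts, sid)) ||
        length(vec_get(repo$objval_stmts, sid))) {
      stop("cannot retract property typing of <", st$subject,
           ">: the property has live values")
    }
  }
  eff_env <- new.env(parent = emptyenv()); eff_env$eff <- new_effect()
  do_retract(repo, stmt_id, eff_env)
  invisible(eff_env$eff)
}

# Core soft-delete of a statement row + dependent structural rows; no guards.
do_retract <- function(repo, stmt_id, eff_env) {
  stab <- repo$tables$statements
  if (gtab_get(stab, "deleted", stmt_id)) return(invisible(NULL))
  sid <- gtab_get(stab, "subject_id", stmt_id)
  pid <- gtab_get(stab, "predicate_id", stmt_id)
  oid <- gtab_get(stab, "object_id", stmt_id)
  lex <- gtab_get(stab, "object_lex", stmt_id)
  lit_type <- gtab_get(stab, "lit_type", stmt_id)
  gtab_set(stab, "deleted", stmt_id, TRUE)
  eff_env$eff <- eff_add(eff_env$eff, "flagged", "statements")
  key <- stmt_keys(sid, pid, oid, lit_type, lex)
  if (exists(key, envir = repo$stmt_key)) rm(list = key, envir = repo$stmt_key)
  inc_count(repo$pred_count, pid, -1L)
  update_kind(repo, pid, eff_env)
  pred <- res_iri_of(repo, pid)
  if (pred == IRI_TYPE && !is.na(oid)) {
    cls_before_s <- cls_like_rid(repo, sid)
    cls_before_o <- cls_like_rid(repo, oid)
    vec_drop(repo$types_of, sid, oid)
    vec_drop(repo$type_subj_of, oid, sid)
    if (cls_before_s) inc_count(repo$cls_inst_count, oid, -1L)
    type_kind_updates(repo, sid, oid, cls_before_s, cls_before_o, eff_env)
    set_pair_row(repo, "instance_of", "inst_row", NULL,
                 paste0(sid, "|", oid), FALSE, eff_env)
    repo$hier_stale <- TRUE
  } else if (pred == IRI_SUBCLASS && !is.na(oid)) {
    set_pair_row(repo, "subclass_edges", "sub_row", NULL,
                 paste0(sid, "|", oid), FALSE, eff_env)
    repo$hier_stale <- TRUE
  } else if (pred == IRI_SUBPROP && !is.na(oid)) {
    set_pair_row(repo, "subprop_edges", "subp_row", NULL,
                 paste0(sid, "|", oid), FALSE, eff_env)
    repo$hier_stale <- TRUE
  } else if (pred == IRI_DOMAIN && !is.na(oid)) {
    set_pair_row(repo, "domains", "dom_row", NULL,
                 paste0(sid, "|", oid), FALSE, eff_env)
  } else if (pred == IRI_RANGE && !is.na(oid)) {
    set_pair_row(repo, "ranges", "rng_row", NULL,
                 paste0(sid, "|", oid), FALSE, eff_env)
    refresh_range_tag(repo, sid)
    migrate_values(repo, sid, eff_env)
  } else if (pred == IRI_IMPORTS && !is.na(oid)) {
    set_pair_row(repo, "imports_t", "imp_row", NULL,
                 paste0(res_iri_of(repo, sid), "|", res_iri_of(repo, oid)),
                 FALSE, eff_env)
  } else {
    flag_value_row(repo, stmt_id, eff_env)
  }
  invisible(NULL)
}
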