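# Data extraction: execute the DataExtraction specifications declared in the
# application ontology into XML documents, mirror the whole application into
# a relational SQL script, and ingest ontologies through the bulk path that
# feeds the statements table directly.

#' Extraction specifications declared by an application
#'
#' @param repo An `ontoreg_repo`.
#' @param app_ns Application (model) namespace.
#' @return data.frame with `spec` (instance IRI), `target` (class IRI) and
#'   `recursive`.
#' @export
extraction_specs <- function(repo, app_ns) {
  app <- download_ontology(repo, app_ns)
  g <- mm_graph(app)
  specs <- sort(g_typed(g, MM("DataExtraction")))
  if (!length(specs)) {
    return(data.frame(spec = character(0), target = character(0),
                      recursive = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(specs, function(s) {
    tgt <- g_objs(g, s, MM("extractionClass"))
    data.frame(spec = s,
               target = if (length(tgt)) tgt[1] else NA_character_,
               recursive = g_flag(g, s, MM("recursive")),
               stringsAsFactors = FALSE)
  }))
}

#' Run all declared extractions into XML documents
#'
#' One document per DataExtraction instance; each holds one `record` element
#' per live instance of the target class.  With `recursive = TRUE`,
#' referenced objects are inlined as nested records (each instance expanded
#' at most once per document; later occurrences become references); with
#' `recursive = FALSE`, object values are emitted as `ref` attributes only.
#' Soft-deleted instances and Password fields never appear.  Coded option
#' values carry both their label text and a `code` attribute.
#'
#' @param repo An `ontoreg_repo`.
#' @param app_ns Application (model) namespace.
#' @return Named list (by extraction spec IRI) of XML document strings.
#' @export
run_extractions <- function(repo, app_ns) {
  ex <- extraction_specs(repo, app_ns)
  if (!nrow(ex)) stop("nothing to extract: the application declares no ",
                      "DataExtraction instances")
  app <- download_ontology(repo, app_ns)
  out <- lapply(seq_len(nrow(ex)), function(i)
    extract_xml_one(repo, app, ex$target[i], ex$recursive[i]))
  names(out) <- ex$spec
  out
}

extract_xml_one <- function(repo, app, target, recursive) {
  tid <- res_lookup(repo, target)
  ids <- if (is.na(tid)) integer(0) else instances_of(repo, tid)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             paste0('<extraction class="', xml_escape_attr(target),
                    '" recursive="', tolower(recursive), '">'))
  expanded <- new.env(parent = emptyenv())
  for (i in ids) {
    lines <- c(lines, record_xml(repo, app, i, recursive, expanded, "  "))
  }
  paste(c(lines, "</extraction>", ""), collapse = "\n")
}

record_xml <- function(repo, app, inst_id, recursive, expanded, indent) {
  ds_id <- instance_class_of(repo, inst_id)
  specs <- field_specs(app, res_iri_of(repo, ds_id))
  all_props <- stats::setNames(specs, vapply(specs, function(s) s$property,
                                             character(1)))
  assign(as.character(inst_id), TRUE, envir = expanded)
  vals <- values_of(repo, inst_id)
  out <- paste0(indent, '<record id="', inst_id, '" class="',
                xml_escape_attr(iri_local(res_iri_of(repo, ds_id))), '">')
  for (j in seq_len(nrow(vals))) {
    p <- vals$property[j]
    spec <- all_props[[p]]
    local <- iri_local(p)
    if (!is.null(spec) && identical(spec$widget, "Password")) next
    if (!is.na(vals$lex[j])) {
      out <- c(out, paste0(indent, '  <field name="', xml_escape_attr(local),
                           '">', xml_escape_text(vals$lex[j]), "</field>"))
    } else {
      oid <- vals$object_id[j]
      if (!is.null(spec) && !is.null(spec$options)) {
        hit <- match(vals$object[j], spec$options$iri)
        lab <- if (is.na(hit)) iri_local(vals$object[j]) else
          spec$options$label[hit]
        code <- if (is.na(hit)) NA_character_ else spec$options$code[hit]
        out <- c(out, paste0(indent, '  <field name="',
                             xml_escape_attr(local), '"',
                             if (!is.na(code)) paste0(' code="',
                                                      xml_escape_attr(code),
                                                      '"'),
                             ">", xml_escape_text(lab), "</field>"))
      } else if (oid %in% live_instance_ids(repo)) {
        if (recursive && is.null(get0(as.character(oid), envir = expanded))) {
          out <- c(out,
                   paste0(indent, '  <field name="', xml_escape_attr(local),
                          '">'),
                   record_xml(repo, app, oid, recursive, expanded,
                              paste0(indent, "    ")),
                   paste0(indent, "  </field>"))
        } else {
          out <- c(out, paste0(indent, '  <field name="',
                               xml_escape_attr(local), '" ref="', oid,
                               '"/>'))
        }
      } else {
        out <- c(out, paste0(indent, '  <field name="',
                             xml_escape_attr(local), '" resource="',
                             xml_escape_attr(vals$object[j]), '"/>'))
      }
    }
  }
  c(out, paste0(indent, "</record>"))
}

live_instance_ids <- function(repo) {
  io <- gtab_dt(repo$tables$instance_of)
  io <- io[!io$deleted]
  ids <- unique(io$instance_id)
  ids[!gtab_get(repo$tables$resources, "deleted", ids)]
}

# ---- SQL mirror ------------------------------------------------------------

sql_name <- function(x) {
  n <- tolower(gsub("[^A-Za-z0-9]+", "_", x))
  n <- sub("^_+", "", sub("_+$", "", n))
  if (!nzchar(n) || grepl("^[0-9]", n)) n <- paste0("x", n)
  n
}

SQL_TYPE <- c(string = "VARCHAR(1000)", integer = "INTEGER",
              float = "DOUBLE PRECISION", boolean = "INTEGER",
              date = "DATE", datetime = "TIMESTAMP")

sql_quote <- function(x) paste0("'", gsub("'", "''", x), "'")

# SQL-92 delimited identifiers (names like "case" are reserved words)
qid <- function(x) paste0('"', x, '"')

#' Mirror an application into a relational SQL script
#'
#' Tables become DataStructures and columns become properties: one table per
#' DataStructure, one typed column per datatype property, a foreign-key
#' column per single-valued object property, a link table per multi-valued
#' object property, and one insertion per live instance.  The script is a
#' one-shot snapshot: it executes on an empty database and fails on rerun
#' (primary keys).  Soft-deleted instances and Password fields are excluded.
#'
#' @param repo An `ontoreg_repo`.
#' @param app_ns Application (model) namespace.
#' @return A `relational_script`: the SQL text with attributes `tables`
#'   (mangled name map) and `counts` (rows per table).
#' @export
export_sql <- function(repo, app_ns) {
  app <- download_ontology(repo, app_ns)
  g <- mm_graph(app)
  parts <- app_structures(g)
  tables <- vapply(parts$ds, function(d) sql_name(iri_local(d)), character(1))
  if (anyDuplicated(tables)) {
    stop("identifier collision after name mangling: ",
         paste(unique(tables[duplicated(tables)]), collapse = ", "))
  }
  ddl <- character(0); dml <- character(0)
  counts <- integer(0)
  link_tables <- character(0)
  for (d in parts$ds) {
    tab <- tables[[d]]
    specs <- Filter(function(s) !identical(s$widget, "SubForm") &&
                      !identical(s$widget, "Password") &&
                      !identical(s$widget, "LiteralProperty"),
                    field_specs(app, d))
    # menu properties with this DataStructure as domain are object links too
    menu_links <- Filter(function(m)
      d %in% g_objs(g, m, IRI_DOMAIN), parts$menu_props)
    ds_id <- res_lookup(repo, d)
    ids <- if (is.na(ds_id)) integer(0) else instances_of(repo, ds_id)
    # single- vs multi-valued object links decided from the live data
    obj_props <- c(
      lapply(Filter(function(s) s$is_object || !is.null(s$options), specs),
             function(s) s$property),
      menu_links)
    multi <- vapply(obj_props, function(p) {
      pid <- res_lookup(repo, p)
      if (is.na(pid)) return(FALSE)
      vr <- gtab_dt(repo$tables$value_resource)
      vr <- vr[!vr$deleted & vr$property_id == pid & vr$instance_id %in% ids]
      if (!nrow(vr)) return(FALSE)
      max(table(vr$instance_id)) > 1L
    }, logical(1))
    cols <- c('"id" INTEGER PRIMARY KEY')
    colnames_ <- character(0)
    getters <- list()
    for (s in specs) {
      if (s$is_object || !is.null(s$options)) next
      cn <- sql_name(s$local)
      tag <- if (!is.na(s$value_tag)) s$value_tag else "string"
      cols <- c(cols, paste0(qid(cn), " ", SQL_TYPE[[tag]]))
      colnames_ <- c(colnames_, cn)
      getters[[cn]] <- list(kind = "lit", property = s$property, tag = tag)
    }
    for (k in seq_along(obj_props)) {
      p <- obj_props[[k]]
      cn <- sql_name(iri_local(p))
      if (multi[k]) {
        link_tables <- c(link_tables,
                         paste0("CREATE TABLE ", qid(paste0(tab, "_", cn)), " (",
                                qid(paste0(tab, "_id")), " INTEGER NOT NULL, ",
                                qid(paste0(cn, "_id")), " INTEGER NOT NULL, PRIMARY KEY (",
                                qid(paste0(tab, "_id")), ", ", qid(paste0(cn, "_id")), "));"))
        getters[[paste0("LINK:", cn)]] <- list(kind = "link", property = p,
                                               table = paste0(tab, "_", cn))
      } else {
        cols <- c(cols, paste0(qid(cn), " INTEGER"))
        colnames_ <- c(colnames_, cn)
        getters[[cn]] <- list(kind = "obj", property = p)
      }
    }
    if (anyDuplicated(colnames_)) {
      stop("identifier collision after name mangling in table ", tab, ": ",
           paste(unique(colnames_[duplicated(colnames_)]), collapse = ", "))
    }
    ddl <- c(ddl, paste0("CREATE TABLE ", qid(tab), " (",
                         paste(cols, collapse = ", "), ");"))
    n_rows <- 0L
    for (i in sort(ids)) {
      vals <- values_of(repo, i)
      row_vals <- c(as.character(i))
      for (cn in colnames_) {
        gt <- getters[[cn]]
        v <- vals[vals$property == gt$property, , drop = FALSE]
        cell <- if (!nrow(v)) "NULL"
          else if (gt$kind == "obj") {
            oid <- v$object_id[1]
            if (!is.na(oid)) as.character(oid) else "NULL"
          } else {
            lex <- v$lex[1]
            if (is.na(lex)) "NULL"
            else if (gt$tag %in% c("integer", "float")) lex
            else if (gt$tag == "boolean") (if (lex == "true") "1" else "0")
            else sql_quote(lex)
          }
        row_vals <- c(row_vals, cell)
      }
      dml <- c(dml, paste0("INSERT INTO ", qid(tab), " (\"id\"",
                           if (length(colnames_))
                             paste0(", ", paste(qid(colnames_),
                                                collapse = ", ")),
                           ") VALUES (", paste(row_vals, collapse = ", "),
                           ");"))
      for (gt in getters) {
        if (gt$kind != "link") next
        v <- vals[vals$property == gt$property, , drop = FALSE]
        for (oid in v$object_id[!is.na(v$object_id)]) {
          dml <- c(dml, paste0("INSERT INTO ", qid(gt$table), " VALUES (", i,
                               ", ", oid, ");"))
        }
      }
      n_rows <- n_rows + 1L
    }
    counts[tab] <- n_rows
  }
  script <- paste(c("-- relational mirror generated by ontoreg",
                    ddl, link_tables, dml, ""), collapse = "\n")
  structure(script, tables = stats::setNames(names(tables), tables),
            counts = counts, class = c("relational_script", "character"))
}

#' @export
print.relational_script <- function(x, ...) {
  cat("<relational_script> ", length(attr(x, "counts")), " tables, ",
      sum(attr(x, "counts")), " rows\n", sep = "")
  invisible(x)
}

# ---- bulk load -------------------------------------------------------------

#' Bulk-load an ontology by feeding the statements table directly
#'
#' The fast ingestion path: statements are inserted in bulk with structural
#' propagation deferred, then the structural tables are rebuilt once from the
#' statements and the hierarchy index is batch-built once.  The final
#' repository state is identical to a statement-by-statement upload; on any
#' failure nothing is persisted.
#'
#' @param repo An `ontoreg_repo`.
#' @param document OWL document text (or path), or a [statement_set()].
#' @param dialect Serialization dialect when `document` is text.
#' @return Summary list (namespace, statements inserted), invisibly.
#' @export
ontoload <- function(repo, document, dialect = "rdfxml") {
  ss <- if (inherits(document, "statement_set")) document
        else parse_owl(document, dialect)
  ns <- ss_ontology_iri(ss)
  if (is.na(ns)) stop("document has no ontology header; cannot ontoload")
  if (!nrow(ss)) stop("empty document; nothing to load")
  ss <- skolemize_blanks(ss)
  snap <- repo_snapshot(repo)
  res <- tryCatch({
    s <- as.data.frame(ss)
    # drop triples already live (global deduplication, as in upload)
    keys0 <- stmt_df_keys(repo, s)
    s <- s[is.na(keys0) | !key_live(repo, keys0), , drop = FALSE]
    # resource ids in first-mention order over (subject, predicate, object)
    mention <- as.vector(t(cbind(s$subject, s$predicate,
                                 ifelse(s$obj_kind == "literal",
                                        NA_character_, s$object))))
    mention <- unique(mention[!is.na(mention)])
    for (iri in mention) res_ensure(repo, iri, ns)
    sid <- vapply(s$subject, function(x) res_lookup(repo, x), integer(1))
    pid <- vapply(s$predicate, function(x) res_lookup(repo, x), integer(1))
    oid <- ifelse(s$obj_kind == "literal", NA_integer_,
                  vapply(s$object, function(x)
                    res_lookup(repo, x), integer(1)))
    stab <- repo$tables$statements
    id0 <- gtab_n(stab)
    n <- nrow(s)
    gtab_add_many(stab, list(
      id = id0 + seq_len(n), subject_id = sid, predicate_id = pid,
      object_id = oid,
      object_lex = ifelse(s$obj_kind == "literal", s$object, NA_character_),
      obj_kind = ifelse(s$obj_kind == "literal", "literal", "resource"),
      lit_type = s$lit_type, ontology_ns = rep(ns, n),
      deleted = rep(FALSE, n)))
    rebuild_structural_inplace(repo)
    n
  }, error = function(e) e)
  if (inherits(res, "error")) {
    repo_restore(repo, snap)
    stop("ontoload of <", ns, "> failed, nothing persisted: ",
         conditionMessage(res), call. = FALSE)
  }
  ensure_hierarchy(repo)
  clear_form_cache(repo)
  invisible(list(namespace = ns, inserted = res))
}

stmt_df_keys <- function(repo, s) {
  vapply(seq_len(nrow(s)), function(i) {
    sid <- res_lookup(repo, s$subject[i])
    pid <- res_lookup(repo, s$predicate[i])
    oid <- if (s$obj_kind[i] != "literal") res_lookup(repo, s$object[i])
           else NA_integer_
    if (is.na(sid) || is.na(pid) ||
        (s$obj_kind[i] != "literal" && is.na(oid))) return(NA_character_)
    stmt_keys(sid, pid, oid, s$lit_type[i], s$object[i])
  }, character(1))
}

key_live <- function(repo, keys) {
  vapply(keys, function(k) {
    !is.na(k) && !is.na(get0(k, envir = repo$stmt_key,
                             ifnotfound = NA_integer_))
  }, logical(1))
}

# Recompute every structural table and map from the live statements (the
# deferred-propagation step of the bulk path).  Resource rows (ids, iris,
# deprecation and deletion flags) are preserved; kinds are recomputed.
rebuild_structural_inplace <- function(repo) {
  target <- rebuild_structural(repo)
  protos <- repo_protos()
  res <- repo$tables$resources
  kind_map <- stats::setNames(target$resources$kind, target$resources$id)
  n <- gtab_n(res)
  kinds <- gtab_get(res, "kind", seq_len(n))
  hit <- as.character(seq_len(n)) %in% names(kind_map)
  kinds[hit] <- unname(kind_map[as.character(seq_len(n))[hit]])
  assign("kind", c(kinds, rep(NA_character_, res$.cap - n)), envir = res)
  remake <- function(tabname, dt) {
    repo$tables[[tabname]] <- gtab_from_dt(
      data.table::as.data.table(c(as.list(dt),
                                  list(stmt_id = rep(NA_integer_, nrow(dt)),
                                       deleted = rep(FALSE, nrow(dt))))),
      protos[[tabname]])
  }
  remake("classes", data.frame(resource_id = target$classes))
  remake("properties", data.frame(resource_id = target$properties))
  remake("domains", target$domains)
  remake("ranges", target$ranges)
  remake("subclass_edges", target$subclass_edges)
  remake("subprop_edges", target$subprop_edges)
  remake("instance_of", target$instance_of)
  remake("imports_t", target$imports)
  for (tag in DATATYPE_TAGS) remake(paste0("value_", tag),
                                    target$values[[paste0("value_", tag)]])
  remake("value_resource", target$value_resource)
  # value rows need their statement ids for retraction bookkeeping
  link_value_stmt_ids(repo)
  repo_reindex(repo)
  repo$hier_stale <- TRUE
  invisible(repo)
}

link_value_stmt_ids <- function(repo) {
  st <- gtab_dt(repo$tables$statements)
  live <- st[!st$deleted]
  lit <- live[live$obj_kind == "literal"]
  res_n <- gtab_n(repo$tables$resources)
  for (tag in DATATYPE_TAGS) {
    tabname <- paste0("value_", tag)
    tab <- repo$tables[[tabname]]
    n <- gtab_n(tab)
    if (!n) next
    dt <- gtab_dt(tab)
    # match on (instance, property, canonical lexical)
    key_tab <- paste0(dt$instance_id, "|", dt$property_id, "|", dt$lex)
    lit_can <- suppressWarnings(lexical_canon(lit$object_lex, tag))
    key_st <- paste0(lit$subject_id, "|", lit$predicate_id, "|", lit_can)
    hit <- match(key_tab, key_st)
    assign("stmt_id", c(lit$id[hit], rep(NA_integer_, tab$.cap - n)),
           envir = tab)
  }
  vrt <- repo$tables$value_resource
  if (gtab_n(vrt)) {
    dt <- gtab_dt(vrt)
    nonlit <- live[live$obj_kind != "literal"]
    key_tab <- paste0(dt$instance_id, "|", dt$property_id, "|", dt$object_id)
    key_st <- paste0(nonlit$subject_id, "|", nonlit$predicate_id, "|",
                     nonlit$object_id)
    hit <- match(key_tab, key_st)
    assign("stmt_id", c(nonlit$id[hit], rep(NA_integer_, vrt$.cap - gtab_n(vrt))),
           envir = vrt)
  }
  invisible(repo)
}
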