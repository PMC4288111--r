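# Moving whole ontologies in and out of the repository.  Multi-ontology
# storage is isolated by a namespace column (the ontology IRI) over a single
# shared resource-id space; import relations are maintained in their own
# table.  Statements are globally deduplicated: a triple is owned by the
# first namespace that asserted it.

skolem_prefix <- function(ns) paste0(ns, "#__bnode_")

skolemize_blanks <- function(ss) {
  ns <- ss_ontology_iri(ss)
  s <- as.data.frame(ss)
  pre <- skolem_prefix(ns)
  bs <- is_blank(s$subject)
  s$subject[bs] <- paste0(pre, substring(s$subject[bs], 3L))
  bo <- s$obj_kind == "blank"
  s$object[bo] <- paste0(pre, substring(s$object[bo], 3L))
  s$obj_kind[bo] <- "iri"
  statement_set(s, ns)
}

deskolemize_blanks <- function(ss) {
  ns <- ss_ontology_iri(ss)
  pre <- skolem_prefix(ns)
  s <- as.data.frame(ss)
  bs <- startsWith(s$subject, pre)
  s$subject[bs] <- paste0("_:", substring(s$subject[bs], nchar(pre) + 1L))
  bo <- s$obj_kind == "iri" & startsWith(s$object, pre)
  s$object[bo] <- paste0("_:", substring(s$object[bo], nchar(pre) + 1L))
  s$obj_kind[bo] <- "blank"
  statement_set(s, ns)
}

#' Namespaces currently loaded in a repository
#' @param repo An `ontoreg_repo`.
#' @return Character vector of ontology namespaces with live statements.
#' @export
loaded_namespaces <- function(repo) {
  st <- gtab_dt(repo$tables$statements)
  sort(unique(st$ontology_ns[!st$deleted]))
}

#' Upload an ontology into the repository
#'
#' `mode = "replace"` synchronizes the namespace to exactly the given
#' statement set (statements no longer present are soft-deleted, new ones
#' asserted); `mode = "incremental"` merges additions only.  The whole
#' operation is transactional: a consistency-guard failure (e.g. the new set
#' drops a class that still has live instances) restores the previous state.
#' The hierarchy index is rebuilt once at the end of the bulk load.
#'
#' @param repo An `ontoreg_repo`.
#' @param ss A [statement_set()] with a non-missing ontology IRI.
#' @param mode `"replace"` or `"incremental"`.
#' @param with_imports Also upload the full import closure (resolved through
#'   `resolver`), imported ontologies first.
#' @param resolver Callback `function(iri) statement_set` used when
#'   `with_imports = TRUE`; the built-in metamodel resolves automatically.
#' @return A summary list (namespace, counts of asserted/retracted
#'   statements, propagation warnings), invisibly.
#' @export
upload_ontology <- function(repo, ss, mode = c("replace", "incremental"),
                            with_imports = FALSE, resolver = NULL) {
  mode <- match.arg(mode)
  ns <- ss_ontology_iri(ss)
  if (is.na(ns)) stop("statement set has no ontology IRI; cannot upload")
  if (with_imports) {
    resolver2 <- function(iri) {
      if (identical(iri, METAMODEL_IRI)) return(metamodel_statements())
      if (is.null(resolver)) stop("no resolver for import <", iri, ">")
      resolver(iri)
    }
    closure <- import_closure(ss, resolver2)
    summaries <- lapply(closure, function(part)
      upload_ontology(repo, part, mode = mode, with_imports = FALSE))
    return(invisible(summaries[[length(summaries)]]))
  }
  ss <- skolemize_blanks(ss)
  snap <- repo_snapshot(repo)
  warnings <- character(0)
  n_assert <- 0L; n_retract <- 0L
  result <- tryCatch({
    s <- as.data.frame(ss)
    new_keys <- paste(s$subject, s$predicate, s$object, s$lit_type, sep = "\r")
    cur <- live_statements_df(repo)
    cur <- cur[cur$ontology_ns == ns, , drop = FALSE]
    cur_keys <- paste(cur$subject, cur$predicate, cur$object, cur$lit_type,
                      sep = "\r")
    if (mode == "replace" && nrow(cur)) {
      gone <- cur[!(cur_keys %in% new_keys), , drop = FALSE]
      if (nrow(gone)) {
        # retract instance typings before class/property typings so that a
        # coherent replacement passes the live-instance guards
        is_meta_typing <- gone$predicate == IRI_TYPE &
          gone$object %in% names(METATYPE_MAP)
        gone <- gone[order(is_meta_typing), , drop = FALSE]
        for (i in seq_len(nrow(gone))) {
          retract_statement(repo, as_st_row(gone[i, ]))
          n_retract <- n_retract + 1L
        }
      }
    }
    add <- s[!(new_keys %in% cur_keys), , drop = FALSE]
    for (i in seq_len(nrow(add))) {
      eff <- assert_statement(repo, add[i, ], ns = ns)
      warnings <- c(warnings, eff$warnings)
      n_assert <- n_assert + sum(eff$inserted["statements"], na.rm = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (inherits(result, "error")) {
    repo_restore(repo, snap)
    stop("upload of <", ns, "> refused: ", conditionMessage(result),
         call. = FALSE)
  }
  ensure_hierarchy(repo)   # one batch rebuild at the end of the bulk load
  clear_form_cache(repo)
  invisible(list(namespace = ns, asserted = n_assert, retracted = n_retract,
                 mode = mode, warnings = unique(warnings)))
}

as_st_row <- function(row) {
  data.frame(subject = row$subject, predicate = row$predicate,
             object = row$object,
             obj_kind = if (row$obj_kind == "literal") "literal" else
               if (is_blank(row$object)) "blank" else "iri",
             lit_type = row$lit_type, stringsAsFactors = FALSE)
}

#' Download an ontology from the repository
#'
#' @param repo An `ontoreg_repo`.
#' @param ns Ontology namespace (IRI) to extract.
#' @param with_imports Include the statements of every (transitively)
#'   imported namespace that is loaded.
#' @return A [statement_set()] of the live statements; soft-deleted
#'   statements are never included.
#' @export
download_ontology <- function(repo, ns, with_imports = FALSE) {
  known <- loaded_namespaces(repo)
  if (!(ns %in% known)) {
    stop("namespace <", ns, "> is not loaded; loaded namespaces: ",
         paste(known, collapse = ", "))
  }
  wanted <- ns
  if (with_imports) {
    imp <- gtab_dt(repo$tables$imports_t)
    imp <- imp[!imp$deleted]
    frontier <- ns
    while (length(frontier)) {
      nxt <- unique(imp$imported_iri[imp$importer_iri %in% frontier])
      frontier <- setdiff(nxt, wanted)
      wanted <- union(wanted, frontier)
    }
    wanted <- intersect(wanted, known)
  }
  df <- live_statements_df(repo)
  df <- df[df$ontology_ns %in% wanted, , drop = FALSE]
  rows <- data.frame(subject = df$subject, predicate = df$predicate,
                     object = df$object,
                     obj_kind = ifelse(df$obj_kind == "literal", "literal",
                                       ifelse(is_blank(df$object), "blank",
                                              "iri")),
                     lit_type = df$lit_type, stringsAsFactors = FALSE)
  deskolemize_blanks(statement_set(rows, ns))
}
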