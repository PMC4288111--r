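# The repository: a hybrid relational store for OWL ontologies and their
# instantiated data.  One statements table is the universal interface; one
# table per ontology-language metaclass role (resource, class, property,
# domain, range, subsumption edges, instance-of) plus one value table per
# supported datatype and one for resource-valued properties are kept in sync
# with it by transactional application-level propagation.  Nothing is ever
# physically deleted: every table carries a soft-delete flag.

SCHEMA_VERSION <- "1"

STRUCTURAL_PREDICATES <- c(
  "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
  "http://www.w3.org/2000/01/rdf-schema#subClassOf",
  "http://www.w3.org/2000/01/rdf-schema#subPropertyOf",
  "http://www.w3.org/2000/01/rdf-schema#domain",
  "http://www.w3.org/2000/01/rdf-schema#range",
  "http://www.w3.org/2002/07/owl#imports")

CLASS_KINDS <- c("named_class", "metaclass")
PROPERTY_KINDS <- c("datatype_property", "object_property", "annotation_property")

repo_protos <- function() {
  vt <- list(instance_id = integer(), property_id = integer(),
             lex = character(), stmt_id = integer(), deleted = logical())
  p <- list(
    statements = list(id = integer(), subject_id = integer(),
                      predicate_id = integer(), object_id = integer(),
                      object_lex = character(), obj_kind = character(),
                      lit_type = character(), ontology_ns = character(),
                      deleted = logical()),
    resources = list(id = integer(), iri = character(), kind = character(),
                     ontology_ns = character(), deprecated = logical(),
                     deleted = logical()),
    classes = list(resource_id = integer(), deleted = logical()),
    properties = list(resource_id = integer(), deleted = logical()),
    domains = list(property_id = integer(), class_id = integer(),
                   stmt_id = integer(), deleted = logical()),
    ranges = list(property_id = integer(), range_id = integer(),
                  stmt_id = integer(), deleted = logical()),
    subclass_edges = list(child_id = integer(), parent_id = integer(),
                          stmt_id = integer(), deleted = logical()),
    subprop_edges = list(child_id = integer(), parent_id = integer(),
                         stmt_id = integer(), deleted = logical()),
    instance_of = list(instance_id = integer(), class_id = integer(),
                       stmt_id = integer(), deleted = logical()),
    imports_t = list(importer_iri = character(), imported_iri = character(),
                     stmt_id = integer(), deleted = logical()),
    value_resource = list(instance_id = integer(), property_id = integer(),
                          object_id = integer(), stmt_id = integer(),
                          deleted = logical())
  )
  for (tag in DATATYPE_TAGS) p[[paste0("value_", tag)]] <- vt
  p
}

VALUE_TABLES <- paste0("value_", DATATYPE_TAGS)

#' Initialize (or open) a repository
#'
#' Creates the full hybrid schema and pre-loads the built-in registry
#' metamodel.  With `target = NULL` the repository lives in memory; with a
#' directory path it is persisted there as one plain-text file per table plus
#' a metadata file, and calling [init_repository()] on an existing valid
#' repository is a no-op that simply opens it.
#'
#' @param target `NULL` for an in-memory repository, or a directory path.
#' @return An object of class `ontoreg_repo`.
#' @export
init_repository <- function(target = NULL) {
  if (!is.null(target) && dir.exists(target) &&
      file.exists(file.path(target, "meta.json"))) {
    return(repo_open(target))
  }
  repo <- new.env(parent = emptyenv())
  class(repo) <- "ontoreg_repo"
  repo$schema_version <- SCHEMA_VERSION
  repo$path <- target
  protos <- repo_protos()
  repo$tables <- lapply(protos, gtab_new)
  for (nm in c("res_id", "stmt_key", "types_of", "type_subj_of",
               "pred_count", "cls_inst_count", "class_row", "prop_row",
               "dom_row", "rng_row", "sub_row", "subp_row", "inst_row",
               "imp_row", "val_row", "val_stmts", "objval_stmts",
               "range_tag")) {
    repo[[nm]] <- new.env(parent = emptyenv(), hash = TRUE)
  }
  repo$hier <- NULL
  repo$hier_stale <- TRUE
  repo$notifications <- list()
  repo$notify_hook <- NULL
  upload_ontology(repo, metamodel_statements(), mode = "replace")
  if (!is.null(target)) {
    dir.create(target, recursive = TRUE, showWarnings = FALSE)
    repo_save(repo)
  }
  repo
}

#' @export
print.ontoreg_repo <- function(x, ...) {
  st <- x$tables$statements
  cat("<ontoreg_repo> ", gtab_n(st), " statements (",
      sum(!gtab_get(st, "deleted", seq_len(gtab_n(st)))), " live), ",
      gtab_n(x$tables$resources), " resources",
      if (!is.null(x$path)) paste0(" @ ", x$path), "\n", sep = "")
  invisible(x)
}

#' Persist a repository to its directory
#'
#' @param repo An `ontoreg_repo`.
#' @param path Target directory; defaults to the repository's own path.
#' @return The repository, invisibly.
#' @export
repo_save <- function(repo, path = repo$path) {
  if (is.null(path)) stop("repository has no target directory")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(repo$tables)) {
    data.table::fwrite(gtab_dt(repo$tables[[nm]]),
                       file.path(path, paste0(nm, ".tsv")),
                       sep = "\t", quote = TRUE, na = "NA")
  }
  meta <- list(schema_version = repo$schema_version,
               tables = names(repo$tables))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  repo$path <- path
  invisible(repo)
}

#' Open a persisted repository
#'
#' Refuses directories holding an incompatible schema version and detects
#' corruption (missing tables).
#'
#' @param path Repository directory.
#' @return An `ontoreg_repo`.
#' @export
repo_open <- function(path) {
  metafile <- file.path(path, "meta.json")
  if (!file.exists(metafile)) stop("not a repository (no meta.json): ", path)
  meta <- jsonlite::read_json(metafile, simplifyVector = TRUE)
  if (!identical(as.character(meta$schema_version), SCHEMA_VERSION)) {
    stop("incompatible repository schema version ", meta$schema_version,
         " (this build expects ", SCHEMA_VERSION,
         "); migrate the repository before opening it")
  }
  protos <- repo_protos()
  missing <- names(protos)[!file.exists(file.path(path,
                                                  paste0(names(protos), ".tsv")))]
  if (length(missing)) {
    stop("corrupted repository: missing table(s) ",
         paste(missing, collapse = ", "))
  }
  repo <- new.env(parent = emptyenv())
  class(repo) <- "ontoreg_repo"
  repo$schema_version <- SCHEMA_VERSION
  repo$path <- path
  repo$tables <- lapply(names(protos), function(nm) {
    dt <- data.table::fread(file.path(path, paste0(nm, ".tsv")),
                            sep = "\t", colClasses = vapply(protos[[nm]],
                              function(v) class(v)[1], character(1)),
                            na.strings = "NA")
    gtab_from_dt(dt, protos[[nm]])
  })
  names(repo$tables) <- names(protos)
  repo$hier <- NULL
  repo$hier_stale <- TRUE
  repo$notifications <- list()
  repo$notify_hook <- NULL
  repo_reindex(repo)
  repo
}

# Rebuild every in-memory lookup map from the persisted tables.
repo_reindex <- function(repo) {
  for (nm in c("res_id", "stmt_key", "types_of", "type_subj_of",
               "pred_count", "cls_inst_count", "class_row", "prop_row",
               "dom_row", "rng_row", "sub_row", "subp_row", "inst_row",
               "imp_row", "val_row", "val_stmts", "objval_stmts",
               "range_tag")) {
    repo[[nm]] <- new.env(parent = emptyenv(), hash = TRUE)
  }
  res <- gtab_dt(repo$tables$resources)
  for (i in seq_len(nrow(res))) {
    assign(res$iri[i], res$id[i], envir = repo$res_id)
  }
  st <- gtab_dt(repo$tables$statements)
  live <- st[!st$deleted]
  if (nrow(live)) {
    keys <- stmt_keys(live$subject_id, live$predicate_id, live$object_id,
                      live$lit_type, live$object_lex)
    for (i in seq_len(nrow(live))) {
      assign(keys[i], live$id[i], envir = repo$stmt_key)
      inc_count(repo$pred_count, live$predicate_id[i], 1L)
    }
    tdf <- live[live$predicate_id == res_lookup(repo, IRI_TYPE) &
                  live$obj_kind == "resource"]
    for (i in seq_len(nrow(tdf))) {
      vec_push(repo$types_of, tdf$subject_id[i], tdf$object_id[i])
      vec_push(repo$type_subj_of, tdf$object_id[i], tdf$subject_id[i])
    }
    # class-like instance counters
    for (i in seq_len(nrow(tdf))) {
      if (cls_like_rid(repo, tdf$subject_id[i])) {
        inc_count(repo$cls_inst_count, tdf$object_id[i], 1L)
      }
    }
  }
  # structural row maps
  map_rows <- function(tabname, mapname, keyfun) {
    dt <- gtab_dt(repo$tables[[tabname]])
    for (i in seq_len(nrow(dt))) {
      assign(keyfun(dt, i), i, envir = repo[[mapname]])
    }
  }
  map_rows("classes", "class_row", function(d, i) as.character(d$resource_id[i]))
  map_rows("properties", "prop_row", function(d, i) as.character(d$resource_id[i]))
  map_rows("domains", "dom_row",
           function(d, i) paste0(d$property_id[i], "|", d$class_id[i]))
  map_rows("ranges", "rng_row",
           function(d, i) paste0(d$property_id[i], "|", d$range_id[i]))
  map_rows("subclass_edges", "sub_row",
           function(d, i) paste0(d$child_id[i], "|", d$parent_id[i]))
  map_rows("subprop_edges", "subp_row",
           function(d, i) paste0(d$child_id[i], "|", d$parent_id[i]))
  map_rows("instance_of", "inst_row",
           function(d, i) paste0(d$instance_id[i], "|", d$class_id[i]))
  map_rows("imports_t", "imp_row",
           function(d, i) paste0(d$importer_iri[i], "|", d$imported_iri[i]))
  for (tabname in c(VALUE_TABLES, "value_resource")) {
    dt <- gtab_dt(repo$tables[[tabname]])
    for (i in seq_len(nrow(dt))) {
      if (!dt$deleted[i]) {
        assign(as.character(dt$stmt_id[i]), list(tabname, i),
               envir = repo$val_row)
        if (tabname == "value_resource") {
          vec_push(repo$objval_stmts, dt$property_id[i], dt$stmt_id[i])
        } else {
          vec_push(repo$val_stmts, dt$property_id[i], dt$stmt_id[i])
        }
      }
    }
  }
  # declared range tags
  rg <- gtab_dt(repo$tables$ranges)
  for (pid in unique(rg$property_id[!rg$deleted])) {
    refresh_range_tag(repo, pid)
  }
  invisible(repo)
}

# Deep snapshot for transactional operations (restore on rejection).
repo_snapshot <- function(repo) {
  snap <- list(
    tables = lapply(repo$tables, gtab_copy),
    maps = lapply(c("res_id", "stmt_key", "types_of", "type_subj_of",
                    "pred_count", "cls_inst_count", "class_row", "prop_row",
                    "dom_row", "rng_row", "sub_row", "subp_row", "inst_row",
                    "imp_row", "val_row", "val_stmts", "objval_stmts",
                    "range_tag"),
                  function(nm) env_copy(repo[[nm]])),
    hier = repo$hier, hier_stale = repo$hier_stale,
    notifications = repo$notifications
  )
  names(snap$maps) <- c("res_id", "stmt_key", "types_of", "type_subj_of",
                        "pred_count", "cls_inst_count", "class_row",
                        "prop_row", "dom_row", "rng_row", "sub_row",
                        "subp_row", "inst_row", "imp_row", "val_row",
                        "val_stmts", "objval_stmts", "range_tag")
  snap
}

repo_restore <- function(repo, snap) {
  repo$tables <- snap$tables
  for (nm in names(snap$maps)) repo[[nm]] <- snap$maps[[nm]]
  repo$hier <- snap$hier
  repo$hier_stale <- snap$hier_stale
  repo$notifications <- snap$notifications
  invisible(repo)
}

# ---- tiny map helpers ------------------------------------------------------

inc_count <- function(env, id, by) {
  key <- as.character(id)
  cur <- get0(key, envir = env, ifnotfound = 0L)
  assign(key, cur + by, envir = env)
  invisible(cur + by)
}

get_count <- function(env, id) get0(as.character(id), envir = env,
                                    ifnotfound = 0L)

vec_push <- function(env, id, val) {
  key <- as.character(id)
  cur <- get0(key, envir = env, ifnotfound = integer(0))
  assign(key, c(cur, val), envir = env)
}

vec_drop <- function(env, id, val) {
  key <- as.character(id)
  cur <- get0(key, envir = env, ifnotfound = integer(0))
  hit <- match(val, cur)
  if (!is.na(hit)) assign(key, cur[-hit], envir = env)
}

vec_get <- function(env, id) get0(as.character(id), envir = env,
                                  ifnotfound = integer(0))

stmt_keys <- function(sid, pid, oid, lit_type, lex) {
  objkey <- ifelse(is.na(oid), paste0("L", lit_type, ":", lex),
                   paste0("R", oid))
  paste0(sid, "|", pid, "|", objkey)
}

res_lookup <- function(repo, iri) {
  get0(iri, envir = repo$res_id, ifnotfound = NA_integer_)
}

res_iri_of <- function(repo, ids) {
  gtab_get(repo$tables$resources, "iri", ids)
}
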