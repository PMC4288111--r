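# The stored-procedure-style query API: subclasses, instances, properties,
# domain/range, values.  Transitive queries are answered through the
# nested-set hierarchy index (interval containment), never by recursion.

# Resolve a resource reference (IRI string or id) to a live id.
res_resolve <- function(repo, x, allow_deleted = FALSE) {
  id <- if (is.character(x)) res_lookup(repo, x) else as.integer(x)
  if (is.na(id) || id < 1L || id > gtab_n(repo$tables$resources)) {
    stop("unknown resource: ", x)
  }
  if (!allow_deleted && gtab_get(repo$tables$resources, "deleted", id)) {
    stop("resource is deleted: ", res_iri_of(repo, id))
  }
  id
}

# Rebuild the class/property nested-set indexes if stale ("calculated only
# once after all classes have been inserted": every bulk load marks the index
# stale and the next transitive query triggers exactly one batch build).
ensure_hierarchy <- function(repo) {
  if (!repo$hier_stale && !is.null(repo$hier)) return(invisible(repo$hier))
  repo$hier <- list(class = build_kind_index(repo, "subclass_edges", "classes"),
                    property = build_kind_index(repo, "subprop_edges",
                                                "properties"))
  repo$hier_stale <- FALSE
  invisible(repo$hier)
}

build_kind_index <- function(repo, edge_tab, role_tab) {
  ed <- gtab_dt(repo$tables[[edge_tab]])
  ed <- ed[!ed$deleted]
  role <- gtab_dt(repo$tables[[role_tab]])
  members <- role$resource_id[!role$deleted]
  ed <- ed[ed$child_id %in% members & ed$parent_id %in% members]
  edges <- data.frame(child = ed$child_id, parent = ed$parent_id)
  roots <- sort(setdiff(members, edges$child))
  build_nested_set(edges, roots)
}

#' Force a batch rebuild of the hierarchy index
#' @param repo An `ontoreg_repo`.
#' @return The index list (class and property indexes), invisibly.
#' @export
rebuild_hierarchy <- function(repo) {
  repo$hier_stale <- TRUE
  invisible(ensure_hierarchy(repo))
}

#' Subsumption and instance queries
#'
#' `subclasses_of()` / `subproperties_of()` return direct children by default
#' and interval-indexed transitive descendants with `transitive = TRUE`;
#' `superclasses_of()` is the transitive dual.  `instances_of()` returns the
#' live instances of a class, including (with `transitive = TRUE`) instances
#' of all descendant classes.  `properties_of()` returns the properties whose
#' declared domain is the class; `domain_of()` / `range_of()` the declared
#' domains and ranges of a property; `values_of()` the typed values of an
#' instance from the value tables.
#'
#' @param repo An `ontoreg_repo`.
#' @param class,property,instance Resource IRI or id.
#' @param transitive Use the nested-set index to answer transitively.
#' @return Integer ids (query functions) or a data.frame (`values_of`).
#' @export
subclasses_of <- function(repo, class, transitive = FALSE) {
  id <- res_resolve(repo, class)
  if (!transitive) return(direct_edges(repo, "subclass_edges", parent = id))
  h <- ensure_hierarchy(repo)
  if (!any(h$class$resource_id == id)) return(integer(0))
  descendants(h$class, id)
}

#' @rdname subclasses_of
#' @export
superclasses_of <- function(repo, class, transitive = TRUE) {
  id <- res_resolve(repo, class)
  if (!transitive) return(direct_edges(repo, "subclass_edges", child = id))
  h <- ensure_hierarchy(repo)
  if (!any(h$class$resource_id == id)) return(integer(0))
  ancestors(h$class, id)
}

#' @rdname subclasses_of
#' @export
subproperties_of <- function(repo, property, transitive = FALSE) {
  id <- res_resolve(repo, property)
  if (!transitive) return(direct_edges(repo, "subprop_edges", parent = id))
  h <- ensure_hierarchy(repo)
  if (!any(h$property$resource_id == id)) return(integer(0))
  descendants(h$property, id)
}

direct_edges <- function(repo, tabname, parent = NULL, child = NULL) {
  ed <- gtab_dt(repo$tables[[tabname]])
  ed <- ed[!ed$deleted]
  if (!is.null(parent)) sort(unique(ed$child_id[ed$parent_id == parent]))
  else sort(unique(ed$parent_id[ed$child_id == child]))
}

#' @rdname subclasses_of
#' @export
instances_of <- function(repo, class, transitive = FALSE) {
  id <- res_resolve(repo, class)
  targets <- if (transitive) c(id, subclasses_of(repo, id, transitive = TRUE))
             else id
  io <- gtab_dt(repo$tables$instance_of)
  io <- io[!io$deleted]
  ids <- sort(unique(io$instance_id[io$class_id %in% targets]))
  del <- gtab_get(repo$tables$resources, "deleted", ids)
  ids[!del]
}

#' @rdname subclasses_of
#' @export
properties_of <- function(repo, class) {
  id <- res_resolve(repo, class)
  d <- gtab_dt(repo$tables$domains)
  d <- d[!d$deleted]
  sort(unique(d$property_id[d$class_id == id]))
}

#' @rdname subclasses_of
#' @export
domain_of <- function(repo, property) {
  id <- res_resolve(repo, property)
  d <- gtab_dt(repo$tables$domains)
  d <- d[!d$deleted]
  sort(unique(d$class_id[d$property_id == id]))
}

#' @rdname subclasses_of
#' @export
range_of <- function(repo, property) {
  id <- res_resolve(repo, property)
  d <- gtab_dt(repo$tables$ranges)
  d <- d[!d$deleted]
  sort(unique(d$range_id[d$property_id == id]))
}

#' @rdname subclasses_of
#' @export
values_of <- function(repo, instance, property = NULL) {
  id <- res_resolve(repo, instance, allow_deleted = TRUE)
  pid <- if (!is.null(property)) res_resolve(repo, property) else NULL
  out <- list()
  for (tag in DATATYPE_TAGS) {
    tab <- gtab_dt(repo$tables[[paste0("value_", tag)]])
    tab <- tab[!tab$deleted & tab$instance_id == id]
    if (!is.null(pid)) tab <- tab[tab$property_id == pid]
    if (nrow(tab)) {
      out[[length(out) + 1L]] <- data.frame(
        property_id = tab$property_id,
        property = res_iri_of(repo, tab$property_id),
        tag = tag, lex = tab$lex, object_id = NA_integer_,
        object = NA_character_, stringsAsFactors = FALSE)
    }
  }
  vr <- gtab_dt(repo$tables$value_resource)
  vr <- vr[!vr$deleted & vr$instance_id == id]
  if (!is.null(pid)) vr <- vr[vr$property_id == pid]
  if (nrow(vr)) {
    out[[length(out) + 1L]] <- data.frame(
      property_id = vr$property_id,
      property = res_iri_of(repo, vr$property_id),
      tag = "resource", lex = NA_character_, object_id = vr$object_id,
      object = res_iri_of(repo, vr$object_id), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(property_id = integer(0), property = character(0),
                      tag = character(0), lex = character(0),
                      object_id = integer(0), object = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$property_id, res$lex, res$object_id), , drop = FALSE]
}

#' Mark a class or property as deprecated
#'
#' Deprecation is the editorial alternative to deletion while a project is
#' running: the resource stays queryable, deprecated fields render read-only
#' and are exempt from mandatory checks, and deprecated structures refuse new
#' instances.
#'
#' @param repo An `ontoreg_repo`.
#' @param resource IRI or id.
#' @return The resource id, invisibly.
#' @export
deprecate <- function(repo, resource) {
  id <- res_resolve(repo, resource)
  gtab_set(repo$tables$resources, "deprecated", id, TRUE)
  invisible(id)
}

is_deprecated <- function(repo, id) {
  gtab_get(repo$tables$resources, "deprecated", id)
}
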