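# Canonical structural state, both as incrementally maintained and as rebuilt
# from scratch from the live statements table.  Equality of the two is the
# core consistency contract of the propagation layer.

live_statements_df <- function(repo) {
  st <- gtab_dt(repo$tables$statements)
  st <- st[!st$deleted]
  iri <- gtab_get(repo$tables$resources, "iri",
                  seq_len(gtab_n(repo$tables$resources)))
  data.frame(
    id = st$id,
    subject = iri[st$subject_id],
    predicate = iri[st$predicate_id],
    object = ifelse(st$obj_kind == "literal", st$object_lex,
                    iri[ifelse(is.na(st$object_id), 1L, st$object_id)]),
    obj_kind = ifelse(st$obj_kind == "literal", "literal",
                      ifelse(is_blank(iri[ifelse(is.na(st$object_id), 1L,
                                                 st$object_id)]),
                             "blank", "iri")),
    lit_type = st$lit_type,
    ontology_ns = st$ontology_ns,
    subject_id = st$subject_id, predicate_id = st$predicate_id,
    object_id = st$object_id,
    stringsAsFactors = FALSE)
}

sorted_dt <- function(dt, cols) {
  dt <- data.table::as.data.table(dt)[, cols, with = FALSE]
  data.table::setorderv(dt, cols)
  dt
}

#' Current structural state of the repository
#'
#' Canonical, order-independent view of the live rows of every structural
#' table (soft-deleted rows excluded), suitable for whole-state equality
#' checks against [rebuild_structural()].
#'
#' @param repo An `ontoreg_repo`.
#' @return A named list of sorted data.tables / vectors.
#' @export
structural_state <- function(repo) {
  res <- gtab_dt(repo$tables$resources)
  res <- res[!res$deleted]
  live_pairs <- function(tabname, cols) {
    dt <- gtab_dt(repo$tables[[tabname]])
    sorted_dt(dt[!dt$deleted], cols)
  }
  vals <- lapply(VALUE_TABLES, function(tn)
    live_pairs(tn, c("instance_id", "property_id", "lex")))
  names(vals) <- VALUE_TABLES
  list(
    resources = sorted_dt(res, c("id", "iri", "kind")),
    classes = sort(unlist(gtab_dt(repo$tables$classes)[
      !gtab_dt(repo$tables$classes)$deleted, "resource_id"])),
    properties = sort(unlist(gtab_dt(repo$tables$properties)[
      !gtab_dt(repo$tables$properties)$deleted, "resource_id"])),
    domains = live_pairs("domains", c("property_id", "class_id")),
    ranges = live_pairs("ranges", c("property_id", "range_id")),
    subclass_edges = live_pairs("subclass_edges", c("child_id", "parent_id")),
    subprop_edges = live_pairs("subprop_edges", c("child_id", "parent_id")),
    instance_of = live_pairs("instance_of", c("instance_id", "class_id")),
    imports = live_pairs("imports_t", c("importer_iri", "imported_iri")),
    values = vals,
    value_resource = live_pairs("value_resource",
                                c("instance_id", "property_id", "object_id"))
  )
}

#' Rebuild the structural state from the live statements alone
#'
#' Ignores every incrementally maintained structural table and recomputes the
#' whole structural state from scratch from the live rows of the statements
#' table (resource ids and the resource-level delete/deprecate flags are the
#' only shared inputs).  Serves as the from-scratch oracle for the
#' propagation layer and as the bulk path used by [ontoload()].
#'
#' @param repo An `ontoreg_repo`.
#' @return The same shape as [structural_state()].
#' @export
rebuild_structural <- function(repo) {
  df <- live_statements_df(repo)
  res <- gtab_dt(repo$tables$resources)
  kinds <- if (nrow(df)) kinds_from_statements(df) else
    stats::setNames(character(0), character(0))
  res_kind <- unname(kinds[res$iri])
  bk <- builtin_kinds(res$iri)
  res_kind[!is.na(bk)] <- bk[!is.na(bk)]
  res_kind[is.na(res_kind)] <- "individual"
  live_res <- !res$deleted
  resources <- sorted_dt(data.frame(id = res$id[live_res],
                                    iri = res$iri[live_res],
                                    kind = res_kind[live_res],
                                    stringsAsFactors = FALSE),
                         c("id", "iri", "kind"))
  kind_of_id <- res_kind   # ids are row positions
  classes <- sort(res$id[kind_of_id %in% CLASS_KINDS & live_res])
  properties <- sort(res$id[kind_of_id %in% PROPERTY_KINDS & live_res])
  pick <- function(pred) df[df$predicate == pred & df$obj_kind != "literal", ,
                            drop = FALSE]
  tdf <- pick(IRI_TYPE)
  io <- tdf[is.na(builtin_kinds(tdf$object)), , drop = FALSE]
  dom <- pick(IRI_DOMAIN); rng <- pick(IRI_RANGE)
  sub <- pick(IRI_SUBCLASS); subp <- pick(IRI_SUBPROP)
  imp <- pick(IRI_IMPORTS)
  pair <- function(d, n1, n2) {
    out <- data.frame(a = d$subject_id, b = d$object_id)
    names(out) <- c(n1, n2)
    sorted_dt(unique(out), c(n1, n2))
  }
  # declared range tag per property, same rule as the incremental path
  rng_tag <- new.env(parent = emptyenv())
  if (nrow(rng)) {
    for (p in unique(rng$subject_id)) {
      cand <- sort(rng$object_id[rng$subject_id == p])
      for (rid in cand) {
        tag <- XSD_TO_TAG[res$iri[rid]]
        if (!is.na(tag)) { assign(as.character(p), unname(tag), envir = rng_tag)
          break }
      }
    }
  }
  lits <- df[df$obj_kind == "literal", , drop = FALSE]
  vals <- lapply(DATATYPE_TAGS, function(tag) NULL)
  names(vals) <- DATATYPE_TAGS
  if (nrow(lits)) {
    declared <- vapply(as.character(lits$predicate_id), function(k)
      get0(k, envir = rng_tag, ifnotfound = "string"), character(1))
    ok <- vapply(seq_len(nrow(lits)), function(i)
      lexical_ok(lits$object[i], declared[i]), logical(1))
    host <- ifelse(ok, declared, "string")
    for (tag in unique(host)) {
      sel <- host == tag
      vals[[tag]] <- data.frame(instance_id = lits$subject_id[sel],
                                property_id = lits$predicate_id[sel],
                                lex = lexical_canon(lits$object[sel], tag),
                                stringsAsFactors = FALSE)
    }
  }
  vals_out <- lapply(DATATYPE_TAGS, function(tag) {
    d <- vals[[tag]]
    if (is.null(d)) d <- data.frame(instance_id = integer(0),
                                    property_id = integer(0),
                                    lex = character(0))
    sorted_dt(unique(d), c("instance_id", "property_id", "lex"))
  })
  names(vals_out) <- VALUE_TABLES
  nonstruct <- df$obj_kind != "literal" &
    !(df$predicate %in% STRUCTURAL_PREDICATES)
  vres <- data.frame(instance_id = df$subject_id[nonstruct],
                     property_id = df$predicate_id[nonstruct],
                     object_id = df$object_id[nonstruct])
  list(
    resources = resources,
    classes = classes,
    properties = properties,
    domains = pair(dom, "property_id", "class_id"),
    ranges = pair(rng, "property_id", "range_id"),
    subclass_edges = pair(sub, "child_id", "parent_id"),
    subprop_edges = pair(subp, "child_id", "parent_id"),
    instance_of = pair(io, "instance_id", "class_id"),
    imports = sorted_dt(unique(data.frame(importer_iri = imp$subject,
                                          imported_iri = imp$object,
                                          stringsAsFactors = FALSE)),
                        c("importer_iri", "imported_iri")),
    values = vals_out,
    value_resource = sorted_dt(unique(vres),
                               c("instance_id", "property_id", "object_id"))
  )
}

#' Compare two structural states
#'
#' @param a,b Structural states from [structural_state()] /
#'   [rebuild_structural()].
#' @return Character vector of component names that differ (empty when the
#'   states are identical).
#' @export
structural_diff <- function(a, b) {
  bad <- character(0)
  for (nm in setdiff(names(a), "values")) {
    if (!isTRUE(all.equal(as.data.frame(a[[nm]]), as.data.frame(b[[nm]]),
                          check.attributes = FALSE))) bad <- c(bad, nm)
  }
  for (nm in names(a$values)) {
    if (!isTRUE(all.equal(as.data.frame(a$values[[nm]]),
                          as.data.frame(b$values[[nm]]),
                          check.attributes = FALSE))) {
      bad <- c(bad, paste0("values.", nm))
    }
  }
  bad
}

#' Total physical row count over every table
#'
#' Soft-delete conservation: this number never decreases under any API call.
#'
#' @param repo An `ontoreg_repo`.
#' @return Integer total of physical (live + flagged) rows.
#' @export
physical_row_count <- function(repo) {
  sum(vapply(repo$tables, gtab_n, integer(1)))
}
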