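# Resource classification: map every mentioned resource of a statement set to
# exactly one resource kind.  The same rule set drives the repository's
# incremental kind maintenance (via counters) and the from-scratch structural
# rebuild, so it is written once here as a pure function over statements.

RESOURCE_KINDS <- c("named_class", "metaclass", "datatype_property",
                    "object_property", "annotation_property", "individual",
                    "ontology", "datatype")

BUILTIN_KIND_MAP <- local({
  m <- c("metaclass", "metaclass", "named_class", "named_class", "named_class",
         "named_class", "named_class", "datatype",
         "object_property", "object_property", "object_property",
         "object_property", "object_property", "object_property",
         "annotation_property", "annotation_property", "annotation_property")
  names(m) <- c(
    "http://www.w3.org/2002/07/owl#Class",
    "http://www.w3.org/2000/01/rdf-schema#Class",
    "http://www.w3.org/2002/07/owl#DatatypeProperty",
    "http://www.w3.org/2002/07/owl#ObjectProperty",
    "http://www.w3.org/2002/07/owl#AnnotationProperty",
    "http://www.w3.org/2002/07/owl#Ontology",
    "http://www.w3.org/2000/01/rdf-schema#Resource",
    "http://www.w3.org/2000/01/rdf-schema#Literal",
    "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
    "http://www.w3.org/2000/01/rdf-schema#subClassOf",
    "http://www.w3.org/2000/01/rdf-schema#subPropertyOf",
    "http://www.w3.org/2000/01/rdf-schema#domain",
    "http://www.w3.org/2000/01/rdf-schema#range",
    "http://www.w3.org/2002/07/owl#imports",
    "http://www.w3.org/2000/01/rdf-schema#label",
    "http://www.w3.org/2000/01/rdf-schema#comment",
    "http://www.w3.org/2002/07/owl#versionInfo")
  m
})

builtin_kinds <- function(iris) {
  k <- unname(BUILTIN_KIND_MAP[iris])
  xsd <- startsWith(iris, NS_XSD)
  k[xsd] <- "datatype"
  k
}

# The explicit metatype (if any) a rdf:type object confers on its subject.
METATYPE_MAP <- local({
  m <- c("class", "class", "datatype_property", "object_property",
         "annotation_property", "ontology")
  names(m) <- c("http://www.w3.org/2002/07/owl#Class",
                "http://www.w3.org/2000/01/rdf-schema#Class",
                "http://www.w3.org/2002/07/owl#DatatypeProperty",
                "http://www.w3.org/2002/07/owl#ObjectProperty",
                "http://www.w3.org/2002/07/owl#AnnotationProperty",
                "http://www.w3.org/2002/07/owl#Ontology")
  m
})

#' Classify every resource mentioned in a statement set
#'
#' Classification is total: subjects, predicates and resource objects all
#' receive exactly one kind.  Named classes whose instances are themselves
#' classes are promoted to `metaclass` (this is how the registry metamodel's
#' DataStructure, Application and Reportable behave once an application
#' instantiates them).  Resources carrying contradictory explicit typing
#' (e.g. both class and datatype property) raise a validation error listing
#' the offending statements.
#'
#' @param ss A [statement_set()].
#' @return A named character vector: resource identifier -> kind, with kinds
#'   drawn from `r paste(RESOURCE_KINDS, collapse = ", ")`.
#' @export
classify_resources <- function(ss) {
  kinds_from_statements(as.data.frame(ss))
}

# df: statement data.frame (live statements only when called from the repo).
kinds_from_statements <- function(df) {
  resources <- unique(c(df$subject, df$predicate,
                        df$object[df$obj_kind != "literal"]))
  if (!length(resources)) return(stats::setNames(character(0), character(0)))
  tdf <- df[df$predicate == IRI_TYPE & df$obj_kind != "literal", , drop = FALSE]

  # explicit metatype per subject, contradiction detection
  mt <- unname(METATYPE_MAP[tdf$object])
  keep <- !is.na(mt)
  expl_pairs <- unique(data.frame(subject = tdf$subject[keep],
                                  metatype = mt[keep],
                                  stringsAsFactors = FALSE))
  dup <- expl_pairs$subject[duplicated(expl_pairs$subject)]
  if (length(dup)) {
    lines <- vapply(unique(dup), function(r) {
      paste0(r, ": typed ",
             paste(expl_pairs$metatype[expl_pairs$subject == r],
                   collapse = " and "))
    }, character(1))
    stop("contradictory resource typing:\n  ", paste(lines, collapse = "\n  "))
  }
  expl <- stats::setNames(expl_pairs$metatype, expl_pairs$subject)

  bk <- builtin_kinds(resources)
  names(bk) <- resources

  # class-likeness: explicit class typing, or being the object of rdf:type
  # (excluding the built-in metatype vocabulary itself)
  obj_builtin <- !is.na(builtin_kinds(tdf$object))
  type_objects <- unique(tdf$object[!obj_builtin])
  cls_like <- stats::setNames(rep(FALSE, length(resources)), resources)
  cls_like[names(expl)[expl == "class"]] <- TRUE
  cls_like[type_objects] <- TRUE

  # metaclass promotion: has an instance that is itself class-like
  has_class_instance <- stats::setNames(rep(FALSE, length(resources)), resources)
  if (nrow(tdf)) {
    subj_cls <- cls_like[tdf$subject]
    has_class_instance[unique(tdf$object[subj_cls])] <- TRUE
  }

  e_vec <- unname(expl[resources])
  is_pred <- resources %in% unique(df$predicate)

  out <- rep("individual", length(resources))
  out[is_pred] <- "annotation_property"
  sel_cls <- cls_like[resources]
  out[sel_cls] <- ifelse(has_class_instance[resources][sel_cls],
                         "metaclass", "named_class")
  has_e <- !is.na(e_vec) & e_vec != "class"
  out[has_e] <- e_vec[has_e]
  has_bk <- !is.na(bk)
  out[has_bk] <- bk[has_bk]
  stats::setNames(unname(out), resources)
}

#' Resolve the import closure of an ontology
#'
#' @param root A [statement_set()].
#' @param resolver A function taking an import IRI and returning the imported
#'   ontology as a `statement_set` (or `NULL` when it cannot resolve it).
#' @return A list of statement sets in topological order: every imported
#'   ontology appears before its importer, each exactly once; the root is
#'   last.
#' @export
import_closure <- function(root, resolver) {
  out <- list(); done <- character(0); onstack <- character(0)
  visit <- function(ss, key) {
    if (key %in% onstack) {
      cyc <- c(onstack[seq(match(key, onstack), length(onstack))], key)
      stop("import cycle: ", paste(cyc, collapse = " -> "))
    }
    if (key %in% done) return(invisible(NULL))
    onstack <<- c(onstack, key)
    for (imp in ss_imports(ss)) {
      if (imp %in% done) next
      child <- tryCatch(resolver(imp), error = function(e) NULL)
      if (is.null(child)) stop("unresolvable import: <", imp, ">")
      visit(child, imp)
    }
    onstack <<- setdiff(onstack, key)
    done <<- c(done, key)
    out[[length(out) + 1L]] <<- ss
    invisible(NULL)
  }
  root_key <- ss_ontology_iri(root)
  if (is.na(root_key)) root_key <- "<root>"
  visit(root, root_key)
  out
}
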