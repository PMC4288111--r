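# Statement-level OWL model: the interchange unit consumed by every other
# layer.  A statement set is a normalized data.frame of subject-predicate-
# object assertions plus the ontology header metadata.

#' Build a single statement
#'
#' A statement is one subject-predicate-object assertion.  Subjects are IRIs
#' or blank-node labels (`_:b1`), predicates are always IRIs, objects are
#' IRIs, blank-node labels, or typed literals.
#'
#' @param subject,predicate Character scalars.
#' @param object Character scalar (IRI, blank label, or literal lexical form).
#' @param obj_kind One of `"iri"`, `"blank"`, `"literal"`.  Inferred when
#'   missing: blank labels and absolute IRIs are resources, everything else is
#'   a string literal.
#' @param lit_type For literals, one of the supported datatype tags
#'   (`r paste(DATATYPE_TAGS, collapse = ", ")`); `NA` otherwise.
#' @return A one-row statement data.frame.
#' @export
stmt <- function(subject, predicate, object, obj_kind = NULL, lit_type = NA_character_) {
  if (is.null(obj_kind)) {
    obj_kind <- if (is_blank(object)) "blank"
      else if (is_absolute_iri(object)) "iri"
      else "literal"
    if (obj_kind == "literal" && is.na(lit_type)) lit_type <- "string"
  }
  if (obj_kind == "literal" && !(lit_type %in% DATATYPE_TAGS)) {
    stop("unsupported literal datatype tag: ", lit_type)
  }
  if (obj_kind != "literal") lit_type <- NA_character_
  if (is_blank(predicate) || !is_absolute_iri(predicate)) {
    stop("predicate must be an absolute IRI: ", predicate)
  }
  data.frame(subject = subject, predicate = predicate, object = object,
             obj_kind = obj_kind, lit_type = lit_type,
             stringsAsFactors = FALSE)
}

# Convenience for literal objects.
lit_stmt <- function(subject, predicate, lexical, tag) {
  stmt(subject, predicate, as.character(lexical), "literal", tag)
}

#' Construct a statement set
#'
#' Normalizes (deduplicates and canonically sorts) a collection of statements
#' and attaches the ontology header.  The `imports` attribute is derived from
#' the `owl:imports` statements present, which keeps the two in sync by
#' construction.
#'
#' @param statements A data.frame with columns `subject`, `predicate`,
#'   `object`, `obj_kind`, `lit_type` (e.g. several [stmt()] rows bound
#'   together), or a list of such data.frames.
#' @param ontology_iri The IRI of the ontology these statements define, or
#'   `NA` when the document carries no header.
#' @return An object of class `statement_set`.
#' @export
statement_set <- function(statements = NULL, ontology_iri = NA_character_) {
  if (is.null(statements)) {
    statements <- data.frame(subject = character(), predicate = character(),
                             object = character(), obj_kind = character(),
                             lit_type = character(), stringsAsFactors = FALSE)
  }
  if (is.list(statements) && !is.data.frame(statements)) {
    statements <- do.call(rbind, statements)
  }
  stopifnot(all(c("subject", "predicate", "object", "obj_kind", "lit_type")
                %in% names(statements)))
  statements <- statements[, c("subject", "predicate", "object",
                               "obj_kind", "lit_type")]
  bad <- !(statements$obj_kind %in% c("iri", "blank", "literal"))
  if (any(bad)) stop("invalid obj_kind: ", unique(statements$obj_kind[bad]))
  badt <- statements$obj_kind == "literal" &
    !(statements$lit_type %in% DATATYPE_TAGS)
  if (any(badt)) {
    stop("unsupported literal datatype tag: ",
         paste(unique(statements$lit_type[badt]), collapse = ", "))
  }
  statements$lit_type[statements$obj_kind != "literal"] <- NA_character_
  # Canonical order + exact-duplicate removal.
  key <- paste(statements$subject, statements$predicate, statements$object,
               statements$obj_kind, statements$lit_type, sep = "\r")
  statements <- statements[!duplicated(key), , drop = FALSE]
  ord <- order(statements$subject, statements$predicate, statements$object,
               statements$obj_kind, method = "radix")
  statements <- statements[ord, , drop = FALSE]
  rownames(statements) <- NULL
  imp <- statements$object[statements$predicate == IRI_IMPORTS &
                             statements$obj_kind == "iri"]
  structure(statements,
            ontology_iri = ontology_iri,
            imports = sort(unique(imp)),
            class = c("statement_set", "data.frame"))
}

#' @export
print.statement_set <- function(x, ...) {
  cat("<statement_set> ", nrow(x), " statements",
      if (!is.na(attr(x, "ontology_iri")))
        paste0("; ontology <", attr(x, "ontology_iri"), ">"),
      if (length(attr(x, "imports")))
        paste0("; imports: ", length(attr(x, "imports"))),
      "\n", sep = "")
  invisible(x)
}

#' Ontology header accessors
#' @param ss A `statement_set`.
#' @return The ontology IRI (scalar) or the imports (character vector).
#' @export
ss_ontology_iri <- function(ss) attr(ss, "ontology_iri")

#' @rdname ss_ontology_iri
#' @export
ss_imports <- function(ss) attr(ss, "imports")

# Relabel blank nodes to stable labels _:b1, _:b2, ... in order of first
# appearance in the canonical statement order (skolemization for storage).
canonicalize_blanks <- function(ss) {
  # first-appearance order over canonically sorted statements, subjects first
  seen <- unique(c(ss$subject[is_blank(ss$subject)],
                   ss$object[ss$obj_kind == "blank"]))
  if (!length(seen)) return(ss)
  map <- stats::setNames(paste0("_:b", seq_along(seen)), seen)
  s <- as.data.frame(ss)
  bs <- is_blank(s$subject)
  s$subject[bs] <- map[s$subject[bs]]
  bo <- s$obj_kind == "blank"
  s$object[bo] <- map[s$object[bo]]
  statement_set(s, ss_ontology_iri(ss))
}

#' Compare two statement sets as multisets modulo blank-node relabeling
#'
#' @param a,b `statement_set` objects.
#' @return `TRUE` when both sets contain the same statements after canonical
#'   blank-node relabeling (ontology headers are compared too when both are
#'   present).
#' @export
ss_equal <- function(a, b) {
  a <- canonicalize_blanks(a); b <- canonicalize_blanks(b)
  if (nrow(a) != nrow(b)) return(FALSE)
  key <- function(s) paste(s$subject, s$predicate, s$object, s$obj_kind,
                           ifelse(is.na(s$lit_type), "", s$lit_type), sep = "\r")
  identical(sort(key(a)), sort(key(b)))
}

# Validate that a lexical form is convertible to the given datatype tag.
lexical_ok <- function(lex, tag) {
  switch(tag,
    string   = rep(TRUE, length(lex)),
    integer  = grepl("^[+-]?[0-9]+$", lex),
    float    = !is.na(suppressWarnings(as.numeric(lex))),
    boolean  = lex %in% c("true", "false", "0", "1"),
    date     = {
      ok <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", lex)
      ok[ok] <- !is.na(suppressWarnings(as.Date(lex[ok], optional = TRUE)))
      ok
    },
    datetime = grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}",
                     lex),
    stop("unsupported datatype tag: ", tag))
}

# Canonical lexical form per tag (used for value-row typed columns).
lexical_canon <- function(lex, tag) {
  switch(tag,
    string   = lex,
    integer  = as.character(as.integer(lex)),
    float    = as.character(as.numeric(lex)),
    boolean  = ifelse(lex %in% c("true", "1"), "true", "false"),
    date     = lex,
    datetime = lex)
}
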