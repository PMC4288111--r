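# Well-known vocabularies and the supported literal datatypes.

NS_RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
NS_OWL  <- "http://www.w3.org/2002/07/owl#"
NS_XSD  <- "http://www.w3.org/2001/XMLSchema#"

#' Metamodel namespace
#'
#' The namespace under which the built-in registry metamodel vocabulary
#' (DataStructure, FormElement widgets, web* facets, ...) is declared.
#'
#' @return A single string, the namespace IRI ending in `#`.
#' @export
mm_ns <- function() "http://ontoreg.org/ns/metamodel#"

RDF  <- function(local) paste0(NS_RDF, local)
RDFS <- function(local) paste0(NS_RDFS, local)
OWL  <- function(local) paste0(NS_OWL, local)
XSD  <- function(local) paste0(NS_XSD, local)
MM   <- function(local) paste0(mm_ns(), local)

IRI_TYPE      <- RDF("type")
IRI_SUBCLASS  <- RDFS("subClassOf")
IRI_SUBPROP   <- RDFS("subPropertyOf")
IRI_DOMAIN    <- RDFS("domain")
IRI_RANGE     <- RDFS("range")
IRI_LABEL     <- RDFS("label")
IRI_COMMENT   <- RDFS("comment")
IRI_CLASS     <- OWL("Class")
IRI_RDFSCLASS <- RDFS("Class")
IRI_DTPROP    <- OWL("DatatypeProperty")
IRI_OBJPROP   <- OWL("ObjectProperty")
IRI_ANNPROP   <- OWL("AnnotationProperty")
IRI_ONTOLOGY  <- OWL("Ontology")
IRI_IMPORTS   <- OWL("imports")
IRI_VERSION   <- OWL("versionInfo")

# Supported literal datatypes: closed, practical set.  Each tag owns one value
# table in the repository schema.
DATATYPE_TAGS <- c("string", "integer", "float", "boolean", "date", "datetime")

# XSD IRI -> tag.  Several XSD numeric types collapse onto the same tag.
XSD_TO_TAG <- c(
  "http://www.w3.org/2001/XMLSchema#string"   = "string",
  "http://www.w3.org/2001/XMLSchema#integer"  = "integer",
  "http://www.w3.org/2001/XMLSchema#int"      = "integer",
  "http://www.w3.org/2001/XMLSchema#long"     = "integer",
  "http://www.w3.org/2001/XMLSchema#float"    = "float",
  "http://www.w3.org/2001/XMLSchema#double"   = "float",
  "http://www.w3.org/2001/XMLSchema#decimal"  = "float",
  "http://www.w3.org/2001/XMLSchema#boolean"  = "boolean",
  "http://www.w3.org/2001/XMLSchema#date"     = "date",
  "http://www.w3.org/2001/XMLSchema#dateTime" = "datetime"
)

# Canonical XSD IRI for each tag (used when serializing).
TAG_TO_XSD <- c(
  string   = "http://www.w3.org/2001/XMLSchema#string",
  integer  = "http://www.w3.org/2001/XMLSchema#integer",
  float    = "http://www.w3.org/2001/XMLSchema#double",
  boolean  = "http://www.w3.org/2001/XMLSchema#boolean",
  date     = "http://www.w3.org/2001/XMLSchema#date",
  datetime = "http://www.w3.org/2001/XMLSchema#dateTime"
)

#' Split an IRI into namespace and local name
#'
#' The namespace ends at the last `#` or, failing that, the last `/`.
#'
#' @param iri Character vector of absolute IRIs.
#' @return A list with character vectors `namespace` and `local_name`.
#' @examples
#' iri_split("http://example.org/reg#Case")
#' @export
iri_split <- function(iri) {
  pos <- regexpr("[#/][^#/]*$", iri)
  bad <- pos < 0L
  if (any(bad)) {
    stop("not an absolute IRI with a namespace separator: ",
         paste(iri[bad], collapse = ", "))
  }
  list(namespace  = substr(iri, 1L, pos),
       local_name = substr(iri, pos + 1L, nchar(iri)))
}

#' @rdname iri_split
#' @export
iri_local <- function(iri) iri_split(iri)$local_name

#' @rdname iri_split
#' @export
iri_namespace <- function(iri) iri_split(iri)$namespace

is_blank <- function(x) startsWith(x, "_:")

is_absolute_iri <- function(x) grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x)
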