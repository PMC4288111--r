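# Reading and writing OWL documents.  RDF/XML is the canonical dialect
# (read/write, via xml2); Turtle is supported as a convenience dialect whose
# writer emits sorted N-Triples-style lines (valid Turtle) and whose reader
# accepts the common subset (@prefix, prefixed names, 'a', ';' and ','
# continuations, typed literals).

#' Parse an OWL document into a statement set
#'
#' @param document Document text (single string), or the path of an existing
#'   file to read.
#' @param dialect `"rdfxml"` (canonical) or `"turtle"`.
#' @return A [statement_set()] with the ontology header and imports populated
#'   and blank nodes given stable local labels.
#' @export
parse_owl <- function(document, dialect = c("rdfxml", "turtle")) {
  dialect <- match.arg(dialect)
  if (length(document) == 1L && !grepl("[<\n]", document) &&
      file.exists(document)) {
    document <- paste(readLines(document, warn = FALSE), collapse = "\n")
  }
  ss <- switch(dialect,
               rdfxml = parse_rdfxml(document),
               turtle = parse_turtle(document))
  canonicalize_blanks(ss)
}

#' Serialize a statement set to an OWL document
#'
#' Output is deterministic: statements are emitted in canonical
#' (subject, predicate, object) order, so two serializations of the same set
#' are byte-identical.
#'
#' @param ss A [statement_set()].
#' @param dialect `"rdfxml"` or `"turtle"`.
#' @return Document text as a single string.
#' @export
serialize_owl <- function(ss, dialect = c("rdfxml", "turtle")) {
  dialect <- match.arg(dialect)
  badt <- ss$obj_kind == "literal" & !(ss$lit_type %in% DATATYPE_TAGS)
  if (any(badt)) {
    stop("unsupported literal datatype tag: ",
         paste(unique(ss$lit_type[badt]), collapse = ", "))
  }
  switch(dialect,
         rdfxml = write_rdfxml(ss),
         turtle = write_turtle(ss))
}

# ---- RDF/XML ---------------------------------------------------------------

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
xml_escape_attr <- function(x) gsub('"', "&quot;", xml_escape_text(x), fixed = TRUE)

ncname_ok <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", x)

parse_rdfxml <- function(text) {
  doc <- tryCatch(suppressWarnings(xml2::read_xml(text)),
                  error = function(e) stop("RDF/XML parse error: ",
                                           conditionMessage(e), call. = FALSE))
  nsmap <- xml2::xml_ns(doc)
  root <- xml2::xml_root(doc)
  root_iri <- resolve_elem_iri(root, nsmap)
  base <- xml2::xml_attr(root, "base",
                         ns = c(xml = "http://www.w3.org/XML/1998/namespace"))
  if (is.na(base)) base <- ""
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 64L); acc$n <- 0L; acc$bn <- 0L
  add <- function(row) {
    acc$n <- acc$n + 1L
    if (acc$n > length(acc$rows)) length(acc$rows) <- 2L * length(acc$rows)
    acc$rows[[acc$n]] <- row
  }
  if (!identical(root_iri, RDF("RDF"))) {
    stop("RDF/XML parse error: root element must be rdf:RDF, found <",
         root_iri, ">")
  }
  for (child in xml2::xml_children(root)) {
    parse_rdfxml_node(child, nsmap, base, add, acc)
  }
  rows <- acc$rows[seq_len(acc$n)]
  df <- if (length(rows)) do.call(rbind, rows) else NULL
  onto <- NA_character_
  if (!is.null(df)) {
    hits <- df$subject[df$predicate == IRI_TYPE & df$object == IRI_ONTOLOGY]
    if (length(hits)) onto <- sort(hits)[1L]
  }
  statement_set(df, onto)
}

resolve_elem_iri <- function(node, nsmap) {
  qn <- xml2::xml_name(node, ns = nsmap)
  if (!grepl(":", qn, fixed = TRUE)) {
    stop("RDF/XML parse error: element <", qn, "> has no namespace (line ",
         xml2::xml_path(node), ")")
  }
  parts <- strsplit(qn, ":", fixed = TRUE)[[1L]]
  uri <- nsmap[[parts[1L]]]
  paste0(uri, paste(parts[-1L], collapse = ":"))
}

resolve_ref <- function(ref, base) {
  if (is_absolute_iri(ref)) return(ref)
  if (startsWith(ref, "#") || ref == "") return(paste0(base, ref))
  stop("RDF/XML parse error: cannot resolve relative reference '", ref,
       "' without xml:base")
}

rdf_attr <- function(node, what) {
  xml2::xml_attr(node, what, ns = c(rdf = NS_RDF))
}

parse_rdfxml_node <- function(node, nsmap, base, add, acc) {
  elem_iri <- resolve_elem_iri(node, nsmap)
  about  <- rdf_attr(node, "rdf:about")
  rid    <- rdf_attr(node, "rdf:ID")
  nodeid <- rdf_attr(node, "rdf:nodeID")
  subject <- if (!is.na(about)) resolve_ref(about, base)
    else if (!is.na(rid)) paste0(base, "#", rid)
    else if (!is.na(nodeid)) paste0("_:", nodeid)
    else { acc$bn <- acc$bn + 1L; paste0("_:g", acc$bn) }
  if (!identical(elem_iri, RDF("Description"))) {
    add(stmt(subject, IRI_TYPE, elem_iri, "iri"))
  }
  for (prop in xml2::xml_children(node)) {
    pred <- resolve_elem_iri(prop, nsmap)
    res    <- rdf_attr(prop, "rdf:resource")
    pnode  <- rdf_attr(prop, "rdf:nodeID")
    dtype  <- rdf_attr(prop, "rdf:datatype")
    kids <- xml2::xml_children(prop)
    if (!is.na(res)) {
      add(stmt(subject, pred, resolve_ref(res, base), "iri"))
    } else if (!is.na(pnode)) {
      add(stmt(subject, pred, paste0("_:", pnode), "blank"))
    } else if (length(kids)) {
      if (length(kids) > 1L) {
        stop("RDF/XML parse error: property element <", pred,
             "> has multiple child nodes")
      }
      obj <- parse_rdfxml_node(kids[[1L]], nsmap, base, add, acc)
      add(stmt(subject, pred, obj,
               if (is_blank(obj)) "blank" else "iri"))
    } else {
      lex <- xml2::xml_text(prop)
      tag <- if (is.na(dtype)) "string" else {
        t <- XSD_TO_TAG[dtype]
        if (is.na(t)) stop("unsupported literal datatype: <", dtype, ">")
        unname(t)
      }
      add(lit_stmt(subject, pred, lex, tag))
    }
  }
  subject
}

write_rdfxml <- function(ss) {
  s <- as.data.frame(ss)
  # prefix table over all predicate namespaces (and rdf for the scaffolding)
  pns <- unique(iri_namespace(s$predicate))
  known <- c(rdf = NS_RDF, rdfs = NS_RDFS, owl = NS_OWL, xsd = NS_XSD)
  extra <- sort(setdiff(pns, known))
  pf <- if (length(extra)) {
    c(known, stats::setNames(extra, paste0("ns", seq_along(extra))))
  } else known
  pf_of <- stats::setNames(names(pf), pf)
  out <- character(0)
  out <- c(out, '<?xml version="1.0" encoding="UTF-8"?>')
  decls <- paste0('    xmlns:', names(pf), '="', xml_escape_attr(unname(pf)), '"',
                  collapse = "\n")
  out <- c(out, paste0("<rdf:RDF\n", decls, ">"))
  subj_order <- unique(s$subject)   # already canonically sorted
  for (subj in subj_order) {
    rows <- s[s$subject == subj, , drop = FALSE]
    head <- if (is_blank(subj)) {
      paste0('  <rdf:Description rdf:nodeID="', substring(subj, 3L), '">')
    } else {
      paste0('  <rdf:Description rdf:about="', xml_escape_attr(subj), '">')
    }
    out <- c(out, head)
    for (i in seq_len(nrow(rows))) {
      sp <- iri_split(rows$predicate[i])
      if (!ncname_ok(sp$local_name)) {
        stop("cannot serialize predicate with non-XML local name: ",
             rows$predicate[i])
      }
      tagname <- paste0(pf_of[[sp$namespace]], ":", sp$local_name)
      ok <- rows$obj_kind[i]
      line <- if (ok == "iri") {
        paste0("    <", tagname, ' rdf:resource="',
               xml_escape_attr(rows$object[i]), '"/>')
      } else if (ok == "blank") {
        paste0("    <", tagname, ' rdf:nodeID="',
               substring(rows$object[i], 3L), '"/>')
      } else if (rows$lit_type[i] == "string") {
        paste0("    <", tagname, ">", xml_escape_text(rows$object[i]),
               "</", tagname, ">")
      } else {
        paste0("    <", tagname, ' rdf:datatype="',
               TAG_TO_XSD[[rows$lit_type[i]]], '">',
               xml_escape_text(rows$object[i]), "</", tagname, ">")
      }
      out <- c(out, line)
    }
    out <- c(out, "  </rdf:Description>")
  }
  out <- c(out, "</rdf:RDF>", "")
  paste(out, collapse = "\n")
}

# ---- Turtle ----------------------------------------------------------------

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}
ttl_unescape <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "", fixed = TRUE)[[1L]]
    res <- character(0); j <- 1L
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        res <- c(res, switch(chars[j + 1L],
                             n = "\n", t = "\t", '"' = '"', "\\" = "\\",
                             stop("bad escape \\", chars[j + 1L])))
        j <- j + 2L
      } else { res <- c(res, chars[j]); j <- j + 1L }
    }
    out[i] <- paste(res, collapse = "")
  }
  out
}

write_turtle <- function(ss) {
  s <- as.data.frame(ss)
  term <- function(x, kind, tag) {
    if (kind == "iri") paste0("<", x, ">")
    else if (kind == "blank") x
    else if (tag == "string") paste0('"', ttl_escape(x), '"')
    else paste0('"', ttl_escape(x), '"^^<', TAG_TO_XSD[[tag]], ">")
  }
  lines <- vapply(seq_len(nrow(s)), function(i) {
    paste(term(s$subject[i], if (is_blank(s$subject[i])) "blank" else "iri", NA),
          paste0("<", s$predicate[i], ">"),
          term(s$object[i], s$obj_kind[i], s$lit_type[i]), ".")
  }, character(1))
  paste(c(lines, ""), collapse = "\n")
}

# Tokenizer for the supported Turtle subset.
ttl_tokens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars); i <- 1L; line <- 1L
  toks <- list(); push <- function(type, val) {
    toks[[length(toks) + 1L]] <<- list(type = type, val = val, line = line)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\n") { line <- line + 1L; i <- i + 1L }
    else if (ch %in% c(" ", "\t", "\r")) i <- i + 1L
    else if (ch == "#") { while (i <= n && chars[i] != "\n") i <- i + 1L }
    else if (ch == "<") {
      j <- i + 1L; while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) stop("Turtle parse error at line ", line, ": unterminated IRI")
      push("iri", paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
    } else if (ch == '"') {
      j <- i + 1L
      while (j <= n && chars[j] != '"') {
        if (chars[j] == "\\") j <- j + 1L
        j <- j + 1L
      }
      if (j > n) stop("Turtle parse error at line ", line,
                      ": unterminated literal")
      lex <- if (j - 1L >= i + 1L) paste(chars[(i + 1L):(j - 1L)],
                                         collapse = "") else ""
      push("lit", ttl_unescape(lex))
      i <- j + 1L
      if (i + 1L <= n && chars[i] == "^" && chars[i + 1L] == "^") {
        push("dtmark", "^^"); i <- i + 2L
      }
    } else if (ch %in% c(".", ";", ",")) { push(ch, ch); i <- i + 1L }
    else {
      j <- i
      while (j <= n && !(chars[j] %in% c(" ", "\t", "\r", "\n", ";", ",",
                                         "#", "<", '"')) &&
             !(chars[j] == "." && (j == n || chars[j + 1L] %in%
                                   c(" ", "\t", "\r", "\n")))) j <- j + 1L
      push("word", paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  toks
}

parse_turtle <- function(text) {
  toks <- ttl_tokens(text)
  prefixes <- c(rdf = NS_RDF, rdfs = NS_RDFS, owl = NS_OWL, xsd = NS_XSD)
  rows <- list(); i <- 1L
  term_of <- function(tok) {
    if (tok$type == "iri") return(list(val = tok$val, kind = "iri"))
    if (tok$type == "word") {
      w <- tok$val
      if (w == "a") return(list(val = IRI_TYPE, kind = "iri"))
      if (startsWith(w, "_:")) return(list(val = w, kind = "blank"))
      m <- regexpr(":", w, fixed = TRUE)
      if (m > 0) {
        pfx <- substr(w, 1L, m - 1L); local <- substring(w, m + 1L)
        if (!pfx %in% names(prefixes)) {
          stop("Turtle parse error at line ", tok$line,
               ": undeclared prefix '", pfx, ":'")
        }
        return(list(val = paste0(prefixes[[pfx]], local), kind = "iri"))
      }
      if (w %in% c("true", "false")) {
        return(list(val = w, kind = "literal", tag = "boolean"))
      }
      if (grepl("^[+-]?[0-9]+$", w)) {
        return(list(val = w, kind = "literal", tag = "integer"))
      }
      if (grepl("^[+-]?[0-9.eE+-]+$", w)) {
        return(list(val = w, kind = "literal", tag = "float"))
      }
      stop("Turtle parse error at line ", tok$line, ": bad term '", w, "'")
    }
    stop("Turtle parse error at line ", tok$line, ": unexpected ", tok$type)
  }
  while (i <= length(toks)) {
    t <- toks[[i]]
    if (t$type == "word" && t$val %in% c("@prefix", "PREFIX")) {
      pfx <- sub(":$", "", toks[[i + 1L]]$val)
      prefixes[pfx] <- toks[[i + 2L]]$val
      i <- i + 3L
      if (i <= length(toks) && toks[[i]]$type == ".") i <- i + 1L
      next
    }
    subj <- term_of(t); i <- i + 1L
    repeat {   # predicate lists separated by ';'
      ptok <- toks[[i]]; pred <- term_of(ptok); i <- i + 1L
      if (pred$kind != "iri") {
        stop("Turtle parse error at line ", ptok$line,
             ": predicate must be an IRI")
      }
      repeat {  # object lists separated by ','
        otok <- toks[[i]]
        if (otok$type == "lit") {
          tag <- "string"
          if (i + 1L <= length(toks) && toks[[i + 1L]]$type == "dtmark") {
            dt <- term_of(toks[[i + 2L]])$val
            tag <- XSD_TO_TAG[dt]
            if (is.na(tag)) stop("unsupported literal datatype: <", dt, ">")
            tag <- unname(tag)
            i <- i + 2L
          }
          rows[[length(rows) + 1L]] <-
            lit_stmt(subj$val, pred$val, otok$val, tag)
        } else {
          obj <- term_of(otok)
          if (!is.null(obj$tag)) {
            rows[[length(rows) + 1L]] <-
              lit_stmt(subj$val, pred$val, obj$val, obj$tag)
          } else {
            rows[[length(rows) + 1L]] <-
              stmt(subj$val, pred$val, obj$val, obj$kind)
          }
        }
        i <- i + 1L
        if (i <= length(toks) && toks[[i]]$type == ",") i <- i + 1L else break
      }
      if (i <= length(toks) && toks[[i]]$type == ";") {
        i <- i + 1L
        # tolerate trailing ';' before '.'
        if (i <= length(toks) && toks[[i]]$type == ".") break
      } else break
    }
    if (i > length(toks) || toks[[i]]$type != ".") {
      stop("Turtle parse error at line ", toks[[min(i, length(toks))]]$line,
           ": expected '.'")
    }
    i <- i + 1L
  }
  df <- if (length(rows)) do.call(rbind, rows) else NULL
  onto <- NA_character_
  if (!is.null(df)) {
    hits <- df$subject[df$predicate == IRI_TYPE & df$object == IRI_ONTOLOGY]
    if (length(hits)) onto <- sort(hits)[1L]
  }
  statement_set(df, onto)
}
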