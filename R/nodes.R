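# Core RDF terms: IRIs, blank nodes, literals, and the canonical ordering
# used everywhere a deterministic sequence is required.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"

XSD_STRING     <- paste0(XSD_NS, "string")
RDF_LANGSTRING <- paste0(RDF_NS, "langString")
RDF_TYPE  <- paste0(RDF_NS, "type")
RDF_FIRST <- paste0(RDF_NS, "first")
RDF_REST  <- paste0(RDF_NS, "rest")
RDF_NIL   <- paste0(RDF_NS, "nil")
RDF_BAG   <- paste0(RDF_NS, "Bag")
RDF_SEQ   <- paste0(RDF_NS, "Seq")
RDF_ALT   <- paste0(RDF_NS, "Alt")
RDFS_SUBCLASSOF    <- paste0(RDFS_NS, "subClassOf")
RDFS_SUBPROPERTYOF <- paste0(RDFS_NS, "subPropertyOf")
RDFS_DOMAIN        <- paste0(RDFS_NS, "domain")
RDFS_RANGE         <- paste0(RDFS_NS, "range")

# Schema-relation predicates handled by the RDFS rules, in their fixed
# output order (placed after ordinary property keys).
SCHEMA_PREDICATES <- c(RDFS_SUBCLASSOF, RDFS_SUBPROPERTYOF, RDFS_DOMAIN, RDFS_RANGE)

rdf2json_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rdf2json_error")))
}

#' Construct an IRI node
#'
#' @param value Absolute IRI string (must contain a scheme, e.g.
#'   `"http://..."` or `"urn:..."`).
#' @return An `rdf_node` of kind `"iri"`.
#' @export
rdf_iri <- function(value) {
  if (!is.character(value) || length(value) != 1L || is.na(value) || !nzchar(value))
    rdf2json_error("IRI must be a non-empty string", "rdf2json_contract_error")
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", value))
    rdf2json_error(sprintf("not an absolute IRI: '%s'", value), "rdf2json_contract_error")
  structure(list(kind = "iri", value = value), class = "rdf_node")
}

#' Construct a blank-node reference
#'
#' @param label Blank-node label, unique within one graph.
#' @return An `rdf_node` of kind `"blank"`.
#' @export
rdf_blank <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label) || !nzchar(label))
    rdf2json_error("blank node label must be a non-empty string", "rdf2json_contract_error")
  structure(list(kind = "blank", value = label), class = "rdf_node")
}

#' Construct a literal node
#'
#' Plain literals normalize to `xsd:string`; language-tagged literals to
#' `rdf:langString`, so every literal carries a datatype.
#'
#' @param lexical Lexical form (the surface string).
#' @param datatype Datatype IRI; defaults to `xsd:string`.
#' @param lang Optional language tag; forces datatype `rdf:langString`.
#' @return An `rdf_node` of kind `"literal"`.
#' @export
rdf_literal <- function(lexical, datatype = XSD_STRING, lang = NULL) {
  if (!is.character(lexical) || length(lexical) != 1L || is.na(lexical))
    rdf2json_error("literal lexical form must be a string", "rdf2json_contract_error")
  if (!is.null(lang) && (!is.character(lang) || !nzchar(lang)))
    rdf2json_error("language tag must be a non-empty string", "rdf2json_contract_error")
  if (!is.null(lang)) datatype <- RDF_LANGSTRING
  if (is.null(datatype) || !nzchar(datatype)) datatype <- XSD_STRING
  structure(list(kind = "literal", value = lexical, datatype = datatype,
                 lang = if (is.null(lang)) NA_character_ else lang),
            class = "rdf_node")
}

#' @export
print.rdf_node <- function(x, ...) {
  cat(switch(x$kind,
    iri = sprintf("<%s>", x$value),
    blank = sprintf("_:%s", x$value),
    literal = {
      s <- sprintf('"%s"', x$value)
      if (!is.na(x$lang)) sprintf("%s@%s", s, x$lang)
      else if (x$datatype != XSD_STRING) sprintf("%s^^<%s>", s, x$datatype)
      else s
    }), "\n")
  invisible(x)
}

node_is_literal <- function(node) inherits(node, "rdf_node") && node$kind == "literal"

# Canonical node ordering: literals < blank nodes < IRIs; within a class,
# lexicographic (byte order, via radix sort) by (lexical, datatype, lang) /
# label / IRI. Vectorized over the triple-table columns.
node_rank <- function(kind) {
  unname(c(literal = 0L, blank = 1L, iri = 2L)[kind])
}

# Order indices of object columns canonically.
order_objects <- function(o_kind, o, o_dt, o_lang) {
  order(node_rank(o_kind), o, o_dt, o_lang, method = "radix")
}
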