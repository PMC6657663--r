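# The mapping rules: pure transformations from graph fragments to JSON
# value structures. Value objects come in five shapes:
#   literal-shape    {"value", "datatype"[, "lang"]}
#   reference-shape  {"rdf:resource"}
#   nested-shape     recursively expanded blank node
#   container-shape  {"rdf:type": "rdf:Bag"|"rdf:Seq"|"rdf:Alt", "rdf:_N"...}
#   collection-shape {"rdf:type": "rdf:List", "items": [...]}

#' Map a namespace table to its JSON object
#'
#' @param ns Named character vector, prefix -> namespace IRI.
#' @return A `jobj` `{prefix: namespace, ...}` in canonical prefix order.
#' @export
map_namespaces <- function(ns) {
  if (length(ns) == 0L) return(jobj())
  ord <- order(names(ns), method = "radix")
  jobj_from(as.list(ns[ord]))
}

# Local names valid for CURIE compaction: no IRI structure characters.
curie_local_ok <- function(local) {
  nzchar(local) & grepl("^[A-Za-z0-9_][A-Za-z0-9_.%-]*$", local)
}

#' Abbreviate an IRI against a namespace map
#'
#' Returns `"prefix:local"` when a declared namespace is a prefix of the
#' IRI and the remainder is a plain local name; the longest matching
#' namespace wins. Otherwise the full IRI is returned.
#'
#' @param iri IRI string or an `rdf_node` of kind `"iri"`.
#' @param ns Named character vector, prefix -> namespace IRI.
#' @return A CURIE or the full IRI string.
#' @export
compact_iri <- function(iri, ns) {
  if (inherits(iri, "rdf_node")) iri <- iri$value
  if (length(ns) == 0L) return(iri)
  hit <- startsWith(iri, ns)
  if (!any(hit)) return(iri)
  cand <- ns[hit]
  cand <- cand[order(-nchar(cand), names(cand), method = "radix")]
  for (i in seq_along(cand)) {
    local <- substring(iri, nchar(cand[[i]]) + 1L)
    if (curie_local_ok(local)) return(paste0(names(cand)[i], ":", local))
  }
  iri
}

#' Map a literal to its value object
#'
#' Literal-shape: `{"value": lexical, "datatype": curie[, "lang": tag]}`.
#' The datatype is always present (plain literals are `xsd:string`,
#' language-tagged ones `rdf:langString`).
#'
#' @param lit An `rdf_node` of kind `"literal"`.
#' @param ns Namespace map used to abbreviate the datatype IRI.
#' @return A literal-shape `jobj`.
#' @export
map_literal <- function(lit, ns) {
  if (!node_is_literal(lit))
    rdf2json_error("map_literal expects a literal node", "rdf2json_contract_error")
  mk_literal_value(lit$value, lit$datatype, if (is.na(lit$lang)) "" else lit$lang, ns)
}

mk_literal_value <- function(lexical, datatype, lang, ns) {
  if (nzchar(lang))
    jobj(value = lexical, datatype = compact_iri(datatype, ns), lang = lang)
  else
    jobj(value = lexical, datatype = compact_iri(datatype, ns))
}

#' Map a URI reference to its value object
#'
#' Reference-shape: `{"rdf:resource": curie-or-iri}`.
#'
#' @param target IRI string or `rdf_node` of kind `"iri"`.
#' @param ns Namespace map.
#' @return A reference-shape `jobj`.
#' @export
map_reference <- function(target, ns) {
  if (inherits(target, "rdf_node")) target <- target$value
  jobj("rdf:resource" = compact_iri(target, ns))
}

#' Merge repeated property values
#'
#' A single value passes through unwrapped; two or more become an array
#' (callers supply values already in canonical order). An array therefore
#' never has fewer than two elements.
#'
#' @param values Non-empty list of value objects for one
#'   (subject, predicate) pair.
#' @return The single value, or a `jarr` of all values.
#' @export
merge_values <- function(values) {
  if (!is.list(values) || length(values) == 0L)
    rdf2json_error("merge_values requires a non-empty list", "rdf2json_contract_error")
  if (length(values) == 1L) values[[1L]] else jarr_from(values)
}

# Fixed output keys and order for the schema relations.
SCHEMA_KEYS <- c("rdfs:subClassOf", "rdfs:subPropertyOf", "rdfs:domain", "rdfs:range")
names(SCHEMA_KEYS) <- SCHEMA_PREDICATES

#' Add RDFS schema relations to a resource object
#'
#' For `rdfs:subClassOf`, `rdfs:subPropertyOf`, `rdfs:domain` and
#' `rdfs:range` triples of `subject`, adds the corresponding key with the
#' superclass/superproperty/domain/range IRI as a plain string value
#' (abbreviated to a CURIE when possible). Multiple values for one relation
#' merge into an array. Schema keys are appended after the ordinary
#' property keys, in the fixed order above.
#'
#' @param resource The partially built `jobj` for `subject`.
#' @param graph An [rdf_graph].
#' @param subject An `rdf_node` (iri or blank).
#' @param ns Namespace map.
#' @return The augmented `jobj`.
#' @export
inject_schema_relations <- function(resource, graph, subject, ns) {
  if (!is_jobj(resource))
    rdf2json_error("resource must be a jobj", "rdf2json_contract_error")
  idx <- subject_rows(graph, subject$kind, subject$value)
  if (length(idx) == 0L) return(resource)
  tr <- graph$triples[idx, , drop = FALSE]
  out <- as.list(resource)
  for (pred in SCHEMA_PREDICATES) {
    rows <- tr[tr$p == pred, , drop = FALSE]
    if (nrow(rows) == 0L) next
    ord <- order_objects(rows$o_kind, rows$o, rows$o_dt, rows$o_lang)
    rows <- rows[ord, , drop = FALSE]
    vals <- lapply(seq_len(nrow(rows)), function(i) {
      if (rows$o_kind[i] == "iri") {
        compact_iri(rows$o[i], ns)
      } else if (rows$o_kind[i] == "literal") {
        warning(sprintf("schema relation <%s> of %s has a literal object (malformed schema)",
                        pred, subject$value), call. = FALSE)
        mk_literal_value(rows$o[i], rows$o_dt[i], rows$o_lang[i], ns)
      } else {
        warning(sprintf("schema relation <%s> of %s has a blank-node object",
                        pred, subject$value), call. = FALSE)
        expand_blank(graph, rdf_blank(rows$o[i]), character(0), ns)
      }
    })
    out[[SCHEMA_KEYS[[pred]]]] <- merge_values(vals)
  }
  jobj_from(out)
}
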