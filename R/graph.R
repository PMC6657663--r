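# The in-memory triple/graph model. Triples live in a character data.frame
# (one row per statement) with set semantics; a hash index from subject key
# to row indices keeps per-resource lookups O(1) so whole-graph migration
# stays near-linear in the number of triples.

triple_columns <- c("s_kind", "s", "p", "o_kind", "o", "o_dt", "o_lang")

empty_triples <- function() {
  as.data.frame(setNames(rep(list(character(0)), length(triple_columns)),
                         triple_columns))
}

# Subject hash key: kind tag + value, so a blank labelled like an IRI can
# never collide with that IRI.
subject_key <- function(kind, value) paste0(substr(kind, 1L, 1L), "|", value)

#' Construct an RDF graph from a triple table
#'
#' @param triples data.frame with columns `s_kind` ("iri"/"blank"), `s`,
#'   `p` (predicate IRI), `o_kind` ("iri"/"blank"/"literal"), `o`,
#'   `o_dt` (datatype IRI, `""` for non-literals), `o_lang` (language tag,
#'   `""` for none). Duplicate rows collapse (set semantics).
#' @param namespaces Named character vector, prefix -> namespace IRI.
#' @return An object of class `rdf_graph`.
#' @export
rdf_graph <- function(triples = empty_triples(), namespaces = character(0)) {
  if (!is.data.frame(triples) || !all(triple_columns %in% names(triples)))
    rdf2json_error("triples must be a data.frame with the triple columns",
                   "rdf2json_contract_error")
  tr <- triples[triple_columns]
  for (cn in triple_columns) tr[[cn]] <- as.character(tr[[cn]])
  if (any(tr$s_kind == "literal"))
    rdf2json_error("a triple subject cannot be a literal", "rdf2json_contract_error")
  tr <- unique(tr)
  # canonical row order: subject (blank<iri, then value), predicate, object
  ord <- order(node_rank(tr$s_kind), tr$s, tr$p,
               node_rank(tr$o_kind), tr$o, tr$o_dt, tr$o_lang,
               method = "radix")
  tr <- tr[ord, , drop = FALSE]
  rownames(tr) <- NULL
  ns <- as.character(namespaces)
  names(ns) <- names(namespaces)
  if (anyDuplicated(names(ns)))
    rdf2json_error("namespace prefixes must be unique", "rdf2json_contract_error")
  g <- structure(list(triples = tr, namespaces = ns), class = "rdf_graph")
  g$index <- build_subject_index(tr)
  g
}

build_subject_index <- function(tr) {
  if (nrow(tr) == 0L) return(new.env(parent = emptyenv()))
  keys <- subject_key(tr$s_kind, tr$s)
  list2env(split(seq_len(nrow(tr)), keys), envir = new.env(parent = emptyenv()))
}

subject_rows <- function(graph, kind, value) {
  idx <- get0(subject_key(kind, value), envir = graph$index,
              inherits = FALSE, ifnotfound = integer(0))
  idx
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat(sprintf("<rdf_graph: %d triples, %d namespace prefixes>\n",
              nrow(x$triples), length(x$namespaces)))
  invisible(x)
}

#' @export
format.rdf_graph <- function(x, ...) {
  sprintf("<rdf_graph: %d triples>", nrow(x$triples))
}

# Convert one triple-table row to the (subject, predicate, object) list form.
row_to_triple <- function(row) {
  obj <- switch(row$o_kind,
    iri = rdf_iri(row$o),
    blank = rdf_blank(row$o),
    literal = rdf_literal(row$o, row$o_dt,
                          if (nzchar(row$o_lang)) row$o_lang else NULL))
  subj <- if (row$s_kind == "blank") rdf_blank(row$s) else rdf_iri(row$s)
  list(subject = subj, predicate = row$p, object = obj)
}

#' Triples with a given subject
#'
#' Returns every triple whose subject equals `node`, in deterministic
#' canonical order (predicate IRI, then object by the canonical node order).
#'
#' @param graph An `rdf_graph`.
#' @param node An `rdf_node` of kind `"iri"` or `"blank"`.
#' @return List of triples; each is `list(subject, predicate, object)`.
#' @export
triples_with_subject <- function(graph, node) {
  if (node_is_literal(node))
    rdf2json_error("a literal cannot be a triple subject", "rdf2json_contract_error")
  idx <- subject_rows(graph, node$kind, node$value)
  if (length(idx) == 0L) return(list())
  tr <- graph$triples[idx, , drop = FALSE]
  ord <- order(tr$p, node_rank(tr$o_kind), tr$o, tr$o_dt, tr$o_lang,
               method = "radix")
  tr <- tr[ord, , drop = FALSE]
  lapply(seq_len(nrow(tr)), function(i) row_to_triple(tr[i, ]))
}

#' Top-level subjects of a graph
#'
#' Distinct subject nodes in canonical order. Blank nodes that occur in
#' object position of any triple are excluded: the blank-node rule inlines
#' them at their reference site. Blank subjects never referenced as objects
#' are kept (they would otherwise be dropped silently).
#'
#' @param graph An `rdf_graph`.
#' @return List of `rdf_node`s (blanks first, then IRIs, each sorted).
#' @export
subjects <- function(graph) {
  tr <- graph$triples
  if (nrow(tr) == 0L) return(list())
  su <- unique(data.frame(kind = tr$s_kind, value = tr$s))
  obj_blanks <- unique(tr$o[tr$o_kind == "blank"])
  keep <- !(su$kind == "blank" & su$value %in% obj_blanks)
  su <- su[keep, , drop = FALSE]
  ord <- order(node_rank(su$kind), su$value, method = "radix")
  su <- su[ord, , drop = FALSE]
  lapply(seq_len(nrow(su)), function(i)
    if (su$kind[i] == "blank") rdf_blank(su$value[i]) else rdf_iri(su$value[i]))
}

#' Detect container / collection structure at a node
#'
#' A node typed `rdf:Bag` / `rdf:Seq` / `rdf:Alt` is a container; a node
#' that is `rdf:nil` or carries an `rdf:first` link is a collection cell.
#' Container typing takes precedence when both patterns are present.
#'
#' @param graph An `rdf_graph`.
#' @param node An `rdf_node` of kind `"iri"` or `"blank"`.
#' @return One of `"plain"`, `"container_bag"`, `"container_seq"`,
#'   `"container_alt"`, `"collection"`.
#' @export
detect_special_node <- function(graph, node) {
  if (node_is_literal(node))
    rdf2json_error("literal nodes cannot be containers", "rdf2json_contract_error")
  if (node$kind == "iri" && node$value == RDF_NIL) return("collection")
  idx <- subject_rows(graph, node$kind, node$value)
  if (length(idx) == 0L) return("plain")
  tr <- graph$triples[idx, , drop = FALSE]
  types <- tr$o[tr$p == RDF_TYPE & tr$o_kind == "iri"]
  if (RDF_BAG %in% types) return("container_bag")
  if (RDF_SEQ %in% types) return("container_seq")
  if (RDF_ALT %in% types) return("container_alt")
  if (any(tr$p == RDF_FIRST)) return("collection")
  "plain"
}

# rdf:_N ordinal predicates; returns N or NA.
ordinal_number <- function(pred) {
  pre <- paste0(RDF_NS, "_")
  n <- rep(NA_integer_, length(pred))
  hit <- startsWith(pred, pre)
  loc <- substring(pred[hit], nchar(pre) + 1L)
  ok <- grepl("^[0-9]+$", loc)
  n[hit][ok] <- as.integer(loc[ok])
  n
}
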