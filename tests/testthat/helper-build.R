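# Small builders used across test files.

NS_RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
NS_XSD <- "http://www.w3.org/2001/XMLSchema#"
NS_EX <- "http://example.org/"

# one triple row as a character vector in table order
tr_row <- function(s_kind, s, p, o_kind, o, o_dt = "", o_lang = "") {
  c(s_kind, s, p, o_kind, o, o_dt, o_lang)
}

graph_of <- function(..., ns = c(ex = NS_EX, rdf = NS_RDF, rdfs = NS_RDFS,
                                 xsd = NS_XSD)) {
  rows <- list(...)
  m <- matrix(unlist(rows), ncol = 7L, byrow = TRUE)
  colnames(m) <- c("s_kind", "s", "p", "o_kind", "o", "o_dt", "o_lang")
  rdf_graph(as.data.frame(m), ns)
}

lit_row <- function(s, p, v, dt = paste0(NS_XSD, "string"), lang = "") {
  if (nzchar(lang)) dt <- paste0(NS_RDF, "langString")
  tr_row("iri", s, p, "literal", v, dt, lang)
}

lit_row_b <- function(s, p, v, dt = paste0(NS_XSD, "string"), lang = "") {
  if (nzchar(lang)) dt <- paste0(NS_RDF, "langString")
  tr_row("blank", s, p, "literal", v, dt, lang)
}

# write turtle text to a temp file, return path
ttl_file <- function(lines) {
  path <- tempfile(fileext = ".ttl")
  writeLines(lines, path)
  path
}

rdfxml_file <- function(lines) {
  path <- tempfile(fileext = ".rdf")
  writeLines(lines, path)
  path
}

# a linear blank-node chain of given depth hanging off one IRI subject
deep_chain_graph <- function(depth) {
  rows <- vector("list", depth + 2L)
  rows[[1L]] <- tr_row("iri", paste0(NS_EX, "root"), paste0(NS_EX, "next"),
                       "blank", "c1")
  for (i in seq_len(depth - 1L))
    rows[[i + 1L]] <- tr_row("blank", sprintf("c%d", i), paste0(NS_EX, "next"),
                             "blank", sprintf("c%d", i + 1L))
  rows[[depth + 1L]] <- tr_row("blank", sprintf("c%d", depth),
                               paste0(NS_EX, "val"), "literal", "leaf",
                               paste0(NS_XSD, "string"), "")
  rows[[depth + 2L]] <- NULL
  do.call(graph_of, rows[!vapply(rows, is.null, TRUE)])
}

# blank-node cycle of given length reachable from an IRI subject
cycle_graph <- function(len) {
  stopifnot(len >= 1L)
  rows <- list(tr_row("iri", paste0(NS_EX, "r"), paste0(NS_EX, "p"),
                      "blank", "B1"))
  for (i in seq_len(len))
    rows[[i + 1L]] <- tr_row("blank", sprintf("B%d", i), paste0(NS_EX, "q"),
                             "blank", sprintf("B%d", (i %% len) + 1L))
  do.call(graph_of, rows)
}

minified <- function(graph) json_serialize(migrate_graph(graph), "minified")
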