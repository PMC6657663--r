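# RDF writers. Used by the fixture generator (scaling series, golden
# fixtures) and by the syntax-invariance tests: a graph written in either
# syntax must reload to the same triple set.

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape_attr <- function(x) gsub('"', "&quot;", xml_escape_text(x), fixed = TRUE)

# Split an IRI into (prefix, local) under the graph's namespace map; the
# local part must be an XML name. Longest namespace wins.
iri_qname <- function(iri, ns) {
  hits <- names(ns)[startsWith(iri, ns)]
  if (length(hits) > 0L) {
    hits <- hits[order(-nchar(ns[hits]))]
    for (h in hits) {
      local <- substring(iri, nchar(ns[[h]]) + 1L)
      if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local))
        return(c(h, local))
    }
  }
  NULL
}

#' Serialize a graph as RDF/XML
#'
#' Writes the flat (unnested) form: one `rdf:Description` element per
#' subject, blank nodes linked through `rdf:nodeID`. Every predicate IRI
#' must be abbreviable under the graph's namespace map (RDF/XML requires
#' QName property elements).
#'
#' @param graph An [rdf_graph].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rdfxml <- function(graph, path) {
  ns <- graph$namespaces
  if (!any(ns == RDF_NS)) ns <- c(ns, rdf = RDF_NS)
  rdfp <- names(ns)[ns == RDF_NS][1L]
  tr <- graph$triples
  decls <- paste0(sprintf(' xmlns:%s="%s"', names(ns), xml_escape_attr(ns)),
                  collapse = "")
  n <- nrow(tr)
  if (n > 0L) {
    # vectorized over triples; subject element boundaries where the key changes
    skey <- subject_key(tr$s_kind, tr$s)
    newsub <- c(TRUE, skey[-1L] != skey[-n])
    qn <- vapply(tr$p, function(p) {
      q <- iri_qname(p, ns)
      if (is.null(q))
        rdf2json_error(sprintf(
          "predicate '%s' has no declared namespace; RDF/XML needs a QName", p),
          "rdf2json_config_error")
      paste0(q[1L], ":", q[2L])
    }, "", USE.NAMES = FALSE)
    lex <- xml_escape_text(tr$o)
    prop <- character(n)
    is_iri <- tr$o_kind == "iri"
    is_blank <- tr$o_kind == "blank"
    is_lang <- tr$o_kind == "literal" & nzchar(tr$o_lang)
    is_dt <- tr$o_kind == "literal" & !is_lang & tr$o_dt != XSD_STRING
    is_plain <- tr$o_kind == "literal" & !is_lang & !is_dt
    prop[is_iri] <- sprintf('    <%s %s:resource="%s"/>', qn[is_iri], rdfp,
                            xml_escape_attr(tr$o[is_iri]))
    prop[is_blank] <- sprintf('    <%s %s:nodeID="%s"/>', qn[is_blank], rdfp,
                              xml_escape_attr(tr$o[is_blank]))
    prop[is_lang] <- sprintf('    <%s xml:lang="%s">%s</%s>', qn[is_lang],
                             xml_escape_attr(tr$o_lang[is_lang]), lex[is_lang],
                             qn[is_lang])
    prop[is_dt] <- sprintf('    <%s %s:datatype="%s">%s</%s>', qn[is_dt], rdfp,
                           xml_escape_attr(tr$o_dt[is_dt]), lex[is_dt], qn[is_dt])
    prop[is_plain] <- sprintf("    <%s>%s</%s>", qn[is_plain], lex[is_plain],
                              qn[is_plain])
    sattr <- ifelse(tr$s_kind == "blank",
                    sprintf(' %s:nodeID="%s"', rdfp, xml_escape_attr(tr$s)),
                    sprintf(' %s:about="%s"', rdfp, xml_escape_attr(tr$s)))
    openel <- sprintf("  <%s:Description%s>", rdfp, sattr)
    closeel <- sprintf("  </%s:Description>", rdfp)
    body <- paste0(ifelse(newsub, paste0(openel, "\n"), ""), prop,
                   ifelse(c(newsub[-1L], TRUE), paste0("\n", closeel), ""))
    out <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf("<%s:RDF%s>", rdfp, decls), body,
             sprintf("</%s:RDF>", rdfp))
  } else {
    out <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf("<%s:RDF%s>", rdfp, decls),
             sprintf("</%s:RDF>", rdfp))
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

ttl_term <- function(kind, value, dt, lang) {
  switch(kind,
    iri = sprintf("<%s>", value),
    blank = sprintf("_:%s", value),
    literal = {
      s <- sprintf('"%s"', ttl_escape(value))
      if (nzchar(lang)) sprintf("%s@%s", s, lang)
      else if (dt != XSD_STRING) sprintf("%s^^<%s>", s, dt)
      else s
    })
}

#' Serialize a graph as Turtle
#'
#' One statement per line, full IRIs (no prefixed names); the namespace map
#' is emitted as `@prefix` directives so it survives a round trip.
#'
#' @param graph An [rdf_graph].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_turtle <- function(graph, path) {
  tr <- graph$triples
  ns <- graph$namespaces
  lines <- sprintf("@prefix %s: <%s> .", names(ns), ns)
  if (nrow(tr) > 0L) {
    subj <- ifelse(tr$s_kind == "blank", paste0("_:", tr$s),
                   sprintf("<%s>", tr$s))
    obj <- vapply(seq_len(nrow(tr)), function(i)
      ttl_term(tr$o_kind[i], tr$o[i], tr$o_dt[i], tr$o_lang[i]), "")
    lines <- c(lines, sprintf("%s <%s> %s .", subj, tr$p, obj))
  }
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
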