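# RDF/XML reader built on xml2. Supports the striped syntax used by
# schema/data documents: rdf:Description and typed node elements,
# rdf:about / rdf:nodeID subjects, rdf:resource / rdf:nodeID objects,
# nested node elements, rdf:parseType="Resource"/"Collection", rdf:li
# ordinals, datatyped and language-tagged literals, property attributes,
# and empty property elements (mapped to the empty-string literal).

# Mutable triple accumulator; rows appended as length-7 character vectors
# into fixed-size chunks (subassigning into one ever-growing list stored in
# an environment would copy it on every write).
ACC_CHUNK <- 1024L

new_acc <- function() {
  e <- new.env(parent = emptyenv())
  e$chunks <- list()
  e$chunk <- vector("list", ACC_CHUNK)
  e$k <- 0L
  e$bn <- 0L
  e
}

acc_emit <- function(acc, s_kind, s, p, o_kind, o, o_dt = "", o_lang = "") {
  k <- acc$k + 1L
  if (k > ACC_CHUNK) {
    acc$chunks[[length(acc$chunks) + 1L]] <- acc$chunk
    acc$chunk <- vector("list", ACC_CHUNK)
    k <- 1L
  }
  acc$chunk[[k]] <- c(s_kind, s, p, o_kind, o, o_dt, o_lang)
  acc$k <- k
}

acc_fresh_blank <- function(acc) {
  acc$bn <- acc$bn + 1L
  sprintf("genid%d", acc$bn)
}

acc_triples <- function(acc) {
  rows <- c(do.call(c, acc$chunks), acc$chunk[seq_len(acc$k)])
  if (length(rows) == 0L) return(empty_triples())
  m <- matrix(unlist(rows, use.names = FALSE), ncol = 7L, byrow = TRUE)
  colnames(m) <- triple_columns
  as.data.frame(m)
}

xml_qname_iri <- function(el, nsmap) {
  nm <- xml2::xml_name(el, ns = nsmap)
  if (!grepl(":", nm, fixed = TRUE))
    rdf2json_error(sprintf("element '%s' has no namespace", nm),
                   "rdf2json_syntax_error")
  i <- regexpr(":", nm, fixed = TRUE)
  prefix <- substr(nm, 1L, i - 1L)
  local <- substring(nm, i + 1L)
  list(iri = paste0(nsmap[[prefix]], local), prefix = prefix, local = local)
}

rx_attrs <- function(el, nsmap) {
  a <- xml2::xml_attrs(el, ns = nsmap)
  a[!startsWith(names(a), "xmlns")]
}

rx_lang <- function(attrs, inherited) {
  if ("xml:lang" %in% names(attrs)) attrs[["xml:lang"]] else inherited
}

RDFXML_SYNTAX_ATTRS <- c("rdf:about", "rdf:ID", "rdf:nodeID", "rdf:resource",
                         "rdf:datatype", "rdf:parseType", "xml:lang")

# Process a node element; returns c(kind, value) of its subject.
rx_node_element <- function(el, acc, nsmap, lang) {
  attrs <- rx_attrs(el, nsmap)
  lang <- rx_lang(attrs, lang)
  if ("rdf:about" %in% names(attrs)) {
    s_kind <- "iri"; s <- attrs[["rdf:about"]]
  } else if ("rdf:nodeID" %in% names(attrs)) {
    s_kind <- "blank"; s <- attrs[["rdf:nodeID"]]
  } else if ("rdf:ID" %in% names(attrs)) {
    rdf2json_error("rdf:ID requires base-IRI resolution, which is not supported; use rdf:about",
                   "rdf2json_syntax_error")
  } else {
    s_kind <- "blank"; s <- acc_fresh_blank(acc)
  }
  q <- xml_qname_iri(el, nsmap)
  if (q$iri != paste0(RDF_NS, "Description"))
    acc_emit(acc, s_kind, s, RDF_TYPE, "iri", q$iri)
  # property attributes (non-syntax attributes) are string literals
  pa <- attrs[!(names(attrs) %in% RDFXML_SYNTAX_ATTRS)]
  for (an in names(pa)) {
    i <- regexpr(":", an, fixed = TRUE)
    if (i < 0L) next
    pred <- paste0(nsmap[[substr(an, 1L, i - 1L)]], substring(an, i + 1L))
    acc_emit(acc, s_kind, s, pred, "literal", pa[[an]], XSD_STRING)
  }
  li <- 0L
  for (pel in xml2::xml_children(el)) {
    li <- rx_property_element(pel, s_kind, s, acc, nsmap, lang, li)
  }
  c(s_kind, s)
}

# Process one property element of subject (s_kind, s); returns updated
# rdf:li counter.
rx_property_element <- function(pel, s_kind, s, acc, nsmap, lang, li) {
  q <- xml_qname_iri(pel, nsmap)
  pred <- q$iri
  if (pred == paste0(RDF_NS, "li")) {
    li <- li + 1L
    pred <- paste0(RDF_NS, "_", li)
  }
  attrs <- rx_attrs(pel, nsmap)
  lang <- rx_lang(attrs, lang)
  if ("rdf:resource" %in% names(attrs)) {
    acc_emit(acc, s_kind, s, pred, "iri", attrs[["rdf:resource"]])
    return(li)
  }
  if ("rdf:nodeID" %in% names(attrs)) {
    acc_emit(acc, s_kind, s, pred, "blank", attrs[["rdf:nodeID"]])
    return(li)
  }
  pt <- if ("rdf:parseType" %in% names(attrs)) attrs[["rdf:parseType"]] else NA
  if (!is.na(pt) && pt == "Resource") {
    b <- acc_fresh_blank(acc)
    acc_emit(acc, s_kind, s, pred, "blank", b)
    lj <- 0L
    for (ch in xml2::xml_children(pel))
      lj <- rx_property_element(ch, "blank", b, acc, nsmap, lang, lj)
    return(li)
  }
  if (!is.na(pt) && pt == "Collection") {
    items <- lapply(xml2::xml_children(pel), rx_node_element,
                    acc = acc, nsmap = nsmap, lang = lang)
    prev_kind <- s_kind; prev <- s; prev_pred <- pred
    for (it in items) {
      cell <- acc_fresh_blank(acc)
      acc_emit(acc, prev_kind, prev, prev_pred, "blank", cell)
      acc_emit(acc, "blank", cell, RDF_FIRST, it[[1L]], it[[2L]])
      prev_kind <- "blank"; prev <- cell; prev_pred <- RDF_REST
    }
    acc_emit(acc, prev_kind, prev, prev_pred, "iri", RDF_NIL)
    return(li)
  }
  if (!is.na(pt) && pt == "Literal") {
    inner <- paste(vapply(xml2::xml_contents(pel), as.character, ""), collapse = "")
    acc_emit(acc, s_kind, s, pred, "literal", inner, paste0(RDF_NS, "XMLLiteral"))
    return(li)
  }
  kids <- xml2::xml_children(pel)
  if (length(kids) > 0L) {
    obj <- rx_node_element(kids[[1L]], acc, nsmap, lang)
    acc_emit(acc, s_kind, s, pred, obj[[1L]], obj[[2L]])
    return(li)
  }
  # literal content; empty element -> empty-string value
  txt <- xml2::xml_text(pel)
  if ("rdf:datatype" %in% names(attrs)) {
    acc_emit(acc, s_kind, s, pred, "literal", txt, attrs[["rdf:datatype"]])
  } else if (!is.null(lang) && !is.na(lang)) {
    acc_emit(acc, s_kind, s, pred, "literal", txt, RDF_LANGSTRING, lang)
  } else {
    acc_emit(acc, s_kind, s, pred, "literal", txt, XSD_STRING)
  }
  li
}

read_rdfxml <- function(path) {
  doc <- tryCatch(suppressWarnings(xml2::read_xml(path, encoding = "UTF-8")),
                  error = function(e)
                    rdf2json_error(sprintf("RDF/XML parse failure in '%s': %s",
                                           path, conditionMessage(e)),
                                   "rdf2json_syntax_error"))
  nsmap <- xml2::xml_ns(doc)
  ns <- as.character(nsmap)
  names(ns) <- names(nsmap)
  ns <- ns[names(ns) != "xml"]
  # attribute lookup needs the reserved xml prefix (xml:lang)
  if (!"xml" %in% names(nsmap))
    nsmap <- structure(c(as.character(nsmap), "http://www.w3.org/XML/1998/namespace"),
                       names = c(names(nsmap), "xml"), class = class(nsmap))
  acc <- new_acc()
  root <- xml2::xml_root(doc)
  rq <- xml_qname_iri(root, nsmap)
  if (rq$iri == paste0(RDF_NS, "RDF")) {
    for (el in xml2::xml_children(root))
      rx_node_element(el, acc, nsmap, NA_character_)
  } else {
    rx_node_element(root, acc, nsmap, NA_character_)
  }
  rdf_graph(acc_triples(acc), ns)
}
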