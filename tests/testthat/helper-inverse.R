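# Inverse interpreter: reads a migrated JSON document back into a triple
# table, and a structural isomorphism check (blank nodes compared by
# signature, not label). Together they test that migration preserves the
# information of cycle-free graphs.

INV_RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
INV_SCHEMA_KEYS <- c("rdfs:subClassOf" = "http://www.w3.org/2000/01/rdf-schema#subClassOf",
                     "rdfs:subPropertyOf" = "http://www.w3.org/2000/01/rdf-schema#subPropertyOf",
                     "rdfs:domain" = "http://www.w3.org/2000/01/rdf-schema#domain",
                     "rdfs:range" = "http://www.w3.org/2000/01/rdf-schema#range")

inverse_graph <- function(json_text) {
  d <- jsonlite::fromJSON(json_text, simplifyVector = FALSE)
  ns <- unlist(d$namespaces)
  if (is.null(ns)) ns <- character(0)
  ec <- function(s) {  # expand a CURIE against the document namespaces
    i <- regexpr(":", s, fixed = TRUE)
    if (i < 0L) return(s)
    px <- substr(s, 1L, i - 1L)
    if (px %in% names(ns)) paste0(ns[[px]], substring(s, i + 1L)) else s
  }
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e$bn <- 0L
  emit <- function(s_kind, s, p, o_kind, o, o_dt = "", o_lang = "")
    e$rows[[length(e$rows) + 1L]] <- c(s_kind, s, p, o_kind, o, o_dt, o_lang)
  fresh <- function() { e$bn <- e$bn + 1L; sprintf("ib%05d", e$bn) }

  interp <- function(s_kind, s, p, v) {
    if (is.character(v)) {  # schema-relation string value
      emit(s_kind, s, p, "iri", ec(v))
      return(invisible())
    }
    stopifnot(is.list(v))
    if (length(v) == 0L) {  # empty description: a blank node with no triples
      emit(s_kind, s, p, "blank", fresh())
      return(invisible())
    }
    if (is.null(names(v))) {  # merged array
      for (el in v) interp(s_kind, s, p, el)
      return(invisible())
    }
    nm <- names(v)
    if ("value" %in% nm) {
      lang <- if ("lang" %in% nm) v$lang else ""
      dt <- ec(v$datatype)
      emit(s_kind, s, p, "literal", v$value, dt, lang)
    } else if ("rdf:resource" %in% nm) {
      emit(s_kind, s, p, "iri", ec(v[["rdf:resource"]]))
    } else if (identical(v[["rdf:type"]], "rdf:List") && "items" %in% nm) {
      items <- v$items
      if (length(items) == 0L) {
        emit(s_kind, s, p, "iri", paste0(INV_RDF, "nil"))
      } else {
        cells <- vapply(seq_along(items), function(.) fresh(), "")
        emit(s_kind, s, p, "blank", cells[1L])
        for (i in seq_along(items)) {
          interp("blank", cells[i], paste0(INV_RDF, "first"), items[[i]])
          if (i < length(items))
            emit("blank", cells[i], paste0(INV_RDF, "rest"), "blank", cells[i + 1L])
          else
            emit("blank", cells[i], paste0(INV_RDF, "rest"), "iri",
                 paste0(INV_RDF, "nil"))
        }
      }
    } else if (is.character(v[["rdf:type"]]) &&
               v[["rdf:type"]] %in% c("rdf:Bag", "rdf:Seq", "rdf:Alt")) {
      b <- fresh()
      emit(s_kind, s, p, "blank", b)
      emit("blank", b, paste0(INV_RDF, "type"), "iri", ec(v[["rdf:type"]]))
      for (k in setdiff(nm, "rdf:type"))
        interp("blank", b, ec(k), v[[k]])
    } else {
      b <- fresh()  # nested blank node
      emit(s_kind, s, p, "blank", b)
      for (k in nm) interp("blank", b, ec(k), v[[k]])
    }
    invisible()
  }

  for (k in names(d$resources)) {
    res <- d$resources[[k]]
    if (startsWith(k, "_:")) { s_kind <- "blank"; s <- substring(k, 3L) }
    else { s_kind <- "iri"; s <- ec(k) }
    for (pk in names(res)) {
      v <- res[[pk]]
      if (pk %in% names(INV_SCHEMA_KEYS) &&
          (is.character(v) || (is.list(v) && is.null(names(v)) &&
                               all(vapply(v, is.character, TRUE))))) {
        for (x in if (is.character(v)) list(v) else v)
          emit(s_kind, s, INV_SCHEMA_KEYS[[pk]], "iri", ec(x))
      } else {
        interp(s_kind, s, ec(pk), v)
      }
    }
  }
  m <- matrix(unlist(e$rows), ncol = 7L, byrow = TRUE,
              dimnames = list(NULL, c("s_kind", "s", "p", "o_kind", "o",
                                      "o_dt", "o_lang")))
  rdf_graph(as.data.frame(m), ns)
}

# Canonical multiset of triples with blank labels replaced by structural
# signatures (cycle-free graphs only).
graph_signature <- function(graph) {
  tr <- graph$triples
  memo <- new.env(parent = emptyenv())
  sig_node <- function(kind, val) {
    if (kind != "blank") return(paste0(kind, "|", val))
    hit <- get0(val, envir = memo, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    idx <- which(tr$s_kind == "blank" & tr$s == val)
    parts <- sort(vapply(idx, function(i)
      paste(tr$p[i], sig_node(tr$o_kind[i], tr$o[i]), tr$o_dt[i], tr$o_lang[i],
            sep = "\r"), ""))
    s <- paste0("{", paste(parts, collapse = ";"), "}")
    assign(val, s, envir = memo)
    s
  }
  sort(vapply(seq_len(nrow(tr)), function(i)
    paste(sig_node(tr$s_kind[i], tr$s[i]), tr$p[i],
          sig_node(tr$o_kind[i], tr$o[i]), tr$o_dt[i], tr$o_lang[i],
          sep = "\n"), ""))
}

graphs_isomorphic <- function(g1, g2) {
  identical(graph_signature(g1), graph_signature(g2))
}
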