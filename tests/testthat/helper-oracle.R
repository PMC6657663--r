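# Independent brute-force mapper: a per-triple, data.frame-scanning,
# recursive implementation of the mapping rules producing plain named
# lists, serialized with jsonlite. Used as the oracle that migrate_graph's
# engine is compared against (as canonical minified JSON).

ORC_SCHEMA <- c("http://www.w3.org/2000/01/rdf-schema#subClassOf" = "rdfs:subClassOf",
                "http://www.w3.org/2000/01/rdf-schema#subPropertyOf" = "rdfs:subPropertyOf",
                "http://www.w3.org/2000/01/rdf-schema#domain" = "rdfs:domain",
                "http://www.w3.org/2000/01/rdf-schema#range" = "rdfs:range")
ORC_RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"

orc_compact <- function(iri, ns) {
  best <- iri; bestlen <- -1L
  for (px in sort(names(ns))) {
    nsi <- ns[[px]]
    if (startsWith(iri, nsi)) {
      loc <- substring(iri, nchar(nsi) + 1L)
      if (nzchar(loc) && grepl("^[A-Za-z0-9_][A-Za-z0-9_.%-]*$", loc) &&
          nchar(nsi) > bestlen) {
        best <- paste0(px, ":", loc); bestlen <- nchar(nsi)
      }
    }
  }
  best
}

orc_rows <- function(tr, kind, val) {
  tr[tr$s_kind == kind & tr$s == val, , drop = FALSE]
}

orc_rank <- function(kind) c(literal = 0L, blank = 1L, iri = 2L)[kind]

orc_special <- function(tr, kind, val) {
  if (kind == "iri" && val == paste0(ORC_RDF, "nil")) return("collection")
  rows <- orc_rows(tr, kind, val)
  ty <- rows$o[rows$p == paste0(ORC_RDF, "type") & rows$o_kind == "iri"]
  for (k in c("Bag", "Seq", "Alt"))
    if (paste0(ORC_RDF, k) %in% ty) return(paste0("container_", tolower(k)))
  if (any(rows$p == paste0(ORC_RDF, "first"))) return("collection")
  "plain"
}

orc_value <- function(tr, ns, o_kind, o, o_dt, o_lang, path) {
  if (o_kind == "literal") {
    v <- list(value = o, datatype = orc_compact(o_dt, ns))
    if (nzchar(o_lang)) v$lang <- o_lang
    return(v)
  }
  if (o_kind == "iri") return(list("rdf:resource" = orc_compact(o, ns)))
  orc_expand(tr, ns, "blank", o, path)
}

orc_expand <- function(tr, ns, kind, val, path, top = FALSE) {
  if (kind == "blank") {
    if (val %in% path) return(list("rdf:nodeID" = val))
    path <- c(path, val)
  }
  sp <- orc_special(tr, kind, val)
  rows <- orc_rows(tr, kind, val)
  if (startsWith(sp, "container_")) {
    tyname <- paste0("rdf:", c(container_bag = "Bag", container_seq = "Seq",
                               container_alt = "Alt")[[sp]])
    out <- list("rdf:type" = tyname)
    ords <- grepl(paste0("^", ORC_RDF, "_[0-9]+$"), rows$p)
    or <- rows[ords, , drop = FALSE]
    if (nrow(or) > 0L) {
      n <- as.integer(sub(".*_", "", or$p))
      or <- or[order(n, orc_rank(or$o_kind), or$o, or$o_dt, or$o_lang,
                     method = "radix"), , drop = FALSE]
      for (i in seq_len(nrow(or)))
        out[[paste0("rdf:_", sub(".*_", "", or$p[i]))]] <-
          orc_value(tr, ns, or$o_kind[i], or$o[i], or$o_dt[i], or$o_lang[i], path)
    }
    # drop exactly the retained container-type triple
    kept_class <- paste0(ORC_RDF, c(container_bag = "Bag", container_seq = "Seq",
                                    container_alt = "Alt")[[sp]])
    drop_i <- which(rows$p == paste0(ORC_RDF, "type") & rows$o_kind == "iri" &
                    rows$o == kept_class)[1L]
    sib <- rows[setdiff(which(!ords), drop_i), , drop = FALSE]
    if (nrow(sib) > 0L) {
      keys <- vapply(sib$p, orc_compact, "", ns = ns)
      for (k in sort(unique(keys))) {
        grp <- sib[keys == k, , drop = FALSE]
        grp <- grp[order(orc_rank(grp$o_kind), grp$o, grp$o_dt, grp$o_lang,
                         method = "radix"), , drop = FALSE]
        vs <- lapply(seq_len(nrow(grp)), function(i)
          orc_value(tr, ns, grp$o_kind[i], grp$o[i], grp$o_dt[i], grp$o_lang[i], path))
        out[[k]] <- if (length(vs) == 1L) vs[[1L]] else vs
      }
    }
    return(out)
  }
  if (sp == "collection") {
    items <- list()
    cur_kind <- kind; cur_val <- val
    seen <- character(0)
    repeat {
      if (cur_kind == "iri" && cur_val == paste0(ORC_RDF, "nil")) break
      ck <- paste0(cur_kind, "|", cur_val)
      if (ck %in% seen) break
      seen <- c(seen, ck)
      cr <- orc_rows(tr, cur_kind, cur_val)
      fr <- cr[cr$p == paste0(ORC_RDF, "first"), , drop = FALSE]
      fr <- fr[order(orc_rank(fr$o_kind), fr$o, fr$o_dt, fr$o_lang,
                     method = "radix"), , drop = FALSE]
      for (i in seq_len(nrow(fr)))
        items[[length(items) + 1L]] <-
          orc_value(tr, ns, fr$o_kind[i], fr$o[i], fr$o_dt[i], fr$o_lang[i], path)
      rr <- cr[cr$p == paste0(ORC_RDF, "rest") & cr$o_kind != "literal", , drop = FALSE]
      if (nrow(rr) == 0L) break
      rr <- rr[order(orc_rank(rr$o_kind), rr$o, method = "radix"), , drop = FALSE]
      cur_kind <- rr$o_kind[nrow(rr)]; cur_val <- rr$o[nrow(rr)]
    }
    return(list("rdf:type" = "rdf:List", items = items))
  }
  # plain resource
  schema <- top & rows$p %in% names(ORC_SCHEMA) & rows$o_kind == "iri"
  ord_rows <- rows[!schema, , drop = FALSE]
  out <- list()
  if (nrow(ord_rows) > 0L) {
    keys <- vapply(ord_rows$p, orc_compact, "", ns = ns)
    for (k in sort(unique(keys), method = "radix")) {
      grp <- ord_rows[keys == k, , drop = FALSE]
      grp <- grp[order(orc_rank(grp$o_kind), grp$o, grp$o_dt, grp$o_lang,
                       method = "radix"), , drop = FALSE]
      vs <- lapply(seq_len(nrow(grp)), function(i)
        orc_value(tr, ns, grp$o_kind[i], grp$o[i], grp$o_dt[i], grp$o_lang[i], path))
      out[[k]] <- if (length(vs) == 1L) vs[[1L]] else vs
    }
  }
  if (any(schema)) {
    sr <- rows[schema, , drop = FALSE]
    for (p in names(ORC_SCHEMA)) {
      grp <- sr[sr$p == p, , drop = FALSE]
      if (nrow(grp) == 0L) next
      vs <- sort(vapply(grp$o, orc_compact, "", ns = ns), method = "radix")
      out[[ORC_SCHEMA[[p]]]] <- if (length(vs) == 1L) vs[[1L]] else as.list(vs)
    }
  }
  if (length(out) == 0L) out <- stats::setNames(list(), character(0))
  out
}

oracle_migrate_json <- function(graph) {
  tr <- graph$triples
  ns <- graph$namespaces
  nsobj <- as.list(ns[order(names(ns), method = "radix")])
  if (length(nsobj) == 0L) nsobj <- stats::setNames(list(), character(0))
  su <- unique(data.frame(kind = tr$s_kind, value = tr$s))
  if (nrow(su) > 0L) {
    objb <- unique(tr$o[tr$o_kind == "blank"])
    su <- su[!(su$kind == "blank" & su$value %in% objb), , drop = FALSE]
    su <- su[order(orc_rank(su$kind), su$value, method = "radix"), , drop = FALSE]
  }
  res <- list()
  for (i in seq_len(nrow(su))) {
    k <- if (su$kind[i] == "blank") paste0("_:", su$value[i])
         else orc_compact(su$value[i], ns)
    res[[k]] <- orc_expand(tr, ns, su$kind[i], su$value[i], character(0),
                           top = orc_special(tr, su$kind[i], su$value[i]) == "plain")
  }
  if (length(res) == 0L) res <- stats::setNames(list(), character(0))
  as.character(jsonlite::toJSON(list(namespaces = nsobj, resources = res),
                                auto_unbox = TRUE))
}
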