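# Hand-written Turtle reader (no Turtle parser exists in the R stack).
# Covers the dialect the package itself emits plus the constructs the
# mapping rules consume: @prefix/@base directives, IRIs, prefixed names,
# blank-node labels and property lists [...], collections (...), 'a',
# predicate-object and object lists (';' / ','), quoted literals with
# escapes, ^^datatype, @lang, and numeric/boolean shorthand.

TTL_TOKEN_RX <- paste0(
  "(?:",
  "#[^\n]*",                                          # comment
  "|<[^<>\\s]*>",                                      # IRIREF
  "|\"(?:[^\"\\\\\n]|\\\\.)*\"",                       # quoted string
  "|@[A-Za-z]+(?:-[A-Za-z0-9]+)*",                     # langtag / directive
  "|\\^\\^",
  "|_:[A-Za-z0-9][A-Za-z0-9_.-]*",                     # blank node label
  "|[+-]?[0-9]+\\.[0-9]+(?:[eE][+-]?[0-9]+)?",         # decimal/double
  "|[+-]?[0-9]+(?:[eE][+-]?[0-9]+)?",                  # integer/double
  "|(?:[A-Za-z_][A-Za-z0-9_.-]*)?:(?:[A-Za-z_][A-Za-z0-9_-]*)?", # pname
  "|[A-Za-z_][A-Za-z0-9_]*",                           # bare word (a, true, false)
  "|[.;,()\\[\\]]",
  ")")

ttl_tokenize <- function(text) {
  m <- gregexpr(TTL_TOKEN_RX, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    toks <- character(0); starts <- integer(0); lens <- integer(0)
  } else {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    toks <- substring(text, starts, starts + lens - 1L)
  }
  # everything between tokens must be whitespace
  gaps <- substring(text,
                    c(1L, starts + lens),
                    c(starts - 1L, nchar(text)))
  bad <- which(grepl("\\S", gaps))
  if (length(bad) > 0L) {
    before <- substr(text, 1L, c(1L, starts + lens)[bad[1L]] - 1L)
    rdf2json_error(sprintf("Turtle syntax error near line %d: unexpected text '%s'",
                           1L + lengths(regmatches(before, gregexpr("\n", before))),
                           trimws(gaps[bad[1L]])),
                   "rdf2json_syntax_error")
  }
  keep <- !startsWith(toks, "#")
  list(toks = toks[keep], starts = starts[keep], text = text)
}

ttl_state <- function(tz) {
  e <- new.env(parent = emptyenv())
  e$toks <- tz$toks; e$starts <- tz$starts; e$text <- tz$text
  e$i <- 1L
  e$ns <- character(0)
  e$acc <- new_acc()
  e
}

ttl_line <- function(st, i) {
  pos <- if (i <= length(st$starts)) st$starts[i] else nchar(st$text)
  before <- substr(st$text, 1L, pos)
  1L + lengths(regmatches(before, gregexpr("\n", before)))
}

ttl_fail <- function(st, what) {
  got <- if (st$i <= length(st$toks)) sprintf("'%s'", st$toks[st$i]) else "end of input"
  rdf2json_error(sprintf("Turtle syntax error at line %d: expected %s, got %s",
                         ttl_line(st, st$i), what, got),
                 "rdf2json_syntax_error")
}

ttl_peek <- function(st) if (st$i <= length(st$toks)) st$toks[st$i] else NA_character_

ttl_next <- function(st) {
  t <- ttl_peek(st)
  if (is.na(t)) ttl_fail(st, "a token")
  st$i <- st$i + 1L
  t
}

ttl_expect <- function(st, tok) {
  t <- ttl_next(st)
  if (t != tok) { st$i <- st$i - 1L; ttl_fail(st, sprintf("'%s'", tok)) }
  t
}

ttl_unescape <- function(s) {
  if (!grepl("\\\\", s)) return(s)
  out <- character(0)
  i <- 1L; n <- nchar(s); buf <- character(0)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch != "\\") { buf <- c(buf, ch); i <- i + 1L; next }
    e <- substr(s, i + 1L, i + 1L)
    if (e == "u") {
      buf <- c(buf, intToUtf8(strtoi(substr(s, i + 2L, i + 5L), 16L)))
      i <- i + 6L
    } else if (e == "U") {
      buf <- c(buf, intToUtf8(strtoi(substr(s, i + 2L, i + 9L), 16L)))
      i <- i + 10L
    } else {
      buf <- c(buf, switch(e, t = "\t", n = "\n", r = "\r", b = "\b",
                           f = "\f", "\"" = "\"", "\\" = "\\", "'" = "'",
                           rdf2json_error(sprintf("bad escape '\\%s'", e),
                                          "rdf2json_syntax_error")))
      i <- i + 2L
    }
  }
  paste(buf, collapse = "")
}

ttl_resolve_pname <- function(st, tok) {
  j <- regexpr(":", tok, fixed = TRUE)
  prefix <- substr(tok, 1L, j - 1L)
  local <- substring(tok, j + 1L)
  if (!(prefix %in% names(st$ns)))
    rdf2json_error(sprintf("undeclared Turtle prefix '%s:'", prefix),
                   "rdf2json_syntax_error")
  paste0(st$ns[[prefix]], local)
}

ttl_iri_tok <- function(st, tok) {
  if (startsWith(tok, "<")) {
    iri <- ttl_unescape(substr(tok, 2L, nchar(tok) - 1L))
    if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", iri))
      rdf2json_error(sprintf("relative IRI '%s' not supported (no base resolution)", iri),
                     "rdf2json_syntax_error")
    iri
  } else if (grepl(":", tok, fixed = TRUE) && !startsWith(tok, "_:")) {
    ttl_resolve_pname(st, tok)
  } else {
    st$i <- st$i - 1L
    ttl_fail(st, "an IRI or prefixed name")
  }
}

# Parse one RDF term in object position; returns c(kind, value, dt, lang).
ttl_object <- function(st) {
  tok <- ttl_next(st)
  if (tok == "[") {
    b <- acc_fresh_blank(st$acc)
    if (ttl_peek(st) != "]") ttl_predicate_object_list(st, "blank", b)
    ttl_expect(st, "]")
    return(c("blank", b, "", ""))
  }
  if (tok == "(") {
    items <- list()
    while (!is.na(ttl_peek(st)) && ttl_peek(st) != ")")
      items[[length(items) + 1L]] <- ttl_object(st)
    ttl_expect(st, ")")
    if (length(items) == 0L) return(c("iri", RDF_NIL, "", ""))
    cells <- vapply(items, function(.) acc_fresh_blank(st$acc), "")
    for (k in seq_along(items)) {
      it <- items[[k]]
      acc_emit(st$acc, "blank", cells[k], RDF_FIRST, it[1L], it[2L], it[3L], it[4L])
      nxt <- if (k < length(items)) c("blank", cells[k + 1L]) else c("iri", RDF_NIL)
      acc_emit(st$acc, "blank", cells[k], RDF_REST, nxt[1L], nxt[2L])
    }
    return(c("blank", cells[1L], "", ""))
  }
  if (startsWith(tok, "_:"))
    return(c("blank", substring(tok, 3L), "", ""))
  if (startsWith(tok, "\"")) {
    lex <- ttl_unescape(substr(tok, 2L, nchar(tok) - 1L))
    nxt <- ttl_peek(st)
    if (!is.na(nxt) && nxt == "^^") {
      ttl_next(st)
      dt <- ttl_iri_tok(st, ttl_next(st))
      return(c("literal", lex, dt, ""))
    }
    if (!is.na(nxt) && startsWith(nxt, "@")) {
      ttl_next(st)
      return(c("literal", lex, RDF_LANGSTRING, substring(nxt, 2L)))
    }
    return(c("literal", lex, XSD_STRING, ""))
  }
  if (grepl("^[+-]?[0-9]", tok)) {
    dt <- if (grepl("[eE]", tok)) paste0(XSD_NS, "double")
          else if (grepl(".", tok, fixed = TRUE)) paste0(XSD_NS, "decimal")
          else paste0(XSD_NS, "integer")
    return(c("literal", tok, dt, ""))
  }
  if (tok %in% c("true", "false"))
    return(c("literal", tok, paste0(XSD_NS, "boolean"), ""))
  c("iri", ttl_iri_tok(st, tok), "", "")
}

ttl_verb <- function(st) {
  tok <- ttl_next(st)
  if (tok == "a") return(RDF_TYPE)
  ttl_iri_tok(st, tok)
}

ttl_predicate_object_list <- function(st, s_kind, s) {
  repeat {
    pred <- ttl_verb(st)
    repeat {
      o <- ttl_object(st)
      acc_emit(st$acc, s_kind, s, pred, o[1L], o[2L], o[3L], o[4L])
      if (identical(ttl_peek(st), ",")) ttl_next(st) else break
    }
    if (identical(ttl_peek(st), ";")) {
      ttl_next(st)
      # dangling ';' before '.' or ']' is legal
      if (is.na(ttl_peek(st)) || ttl_peek(st) %in% c(".", "]")) break
    } else break
  }
}

ttl_statement <- function(st) {
  tok <- ttl_peek(st)
  if (tok %in% c("@prefix", "@base")) {
    ttl_next(st)
    if (tok == "@prefix") {
      pn <- ttl_next(st)
      if (!grepl(":$", pn)) { st$i <- st$i - 1L; ttl_fail(st, "a prefix name") }
      prefix <- substr(pn, 1L, nchar(pn) - 1L)
      iri_tok <- ttl_next(st)
      if (!startsWith(iri_tok, "<")) { st$i <- st$i - 1L; ttl_fail(st, "an IRI") }
      st$ns[[prefix]] <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
    } else {
      ttl_next(st)  # base IRI recorded nowhere: relative IRIs are rejected
    }
    ttl_expect(st, ".")
    return(invisible())
  }
  tok <- ttl_next(st)
  if (tok == "[") {
    b <- acc_fresh_blank(st$acc)
    if (ttl_peek(st) != "]") ttl_predicate_object_list(st, "blank", b)
    ttl_expect(st, "]")
    if (!identical(ttl_peek(st), "."))  # [ ... ] . with trailing properties
      ttl_predicate_object_list(st, "blank", b)
  } else if (startsWith(tok, "_:")) {
    ttl_predicate_object_list(st, "blank", substring(tok, 3L))
  } else {
    s <- ttl_iri_tok(st, tok)
    ttl_predicate_object_list(st, "iri", s)
  }
  ttl_expect(st, ".")
}

read_turtle <- function(path) {
  text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  st <- ttl_state(ttl_tokenize(text))
  while (!is.na(ttl_peek(st))) ttl_statement(st)
  rdf_graph(acc_triples(st$acc), st$ns)
}
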