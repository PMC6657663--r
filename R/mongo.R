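# Document-store import safety. mongoimport field names may not contain
# "." or NUL and may not start with "$"; forbidden characters are replaced
# by fullwidth Unicode homoglyphs so keys stay readable and the mapping is
# injective on the forbidden set.

FULLWIDTH_DOT <- "．"
FULLWIDTH_DOLLAR <- "＄"

#' Default sanitization map
#'
#' `"."` anywhere becomes U+FF0E (fullwidth full stop), a leading `"$"`
#' becomes U+FF04 (fullwidth dollar sign), and NUL characters are removed.
#'
#' @return A named list with entries `dot`, `dollar`, `nul`.
#' @export
default_sanitization_map <- function() {
  list(dot = FULLWIDTH_DOT, dollar = FULLWIDTH_DOLLAR, nul = "")
}

#' Sanitize one field name
#'
#' The result contains no `"."`, no NUL, and does not start with `"$"`;
#' all other characters pass through. Idempotent.
#'
#' @param name Field name.
#' @param map Sanitization map, see [default_sanitization_map].
#' @return The sanitized name.
#' @export
sanitize_field_name <- function(name, map = default_sanitization_map()) {
  out <- gsub(".", map$dot, name, fixed = TRUE)
  out <- sub("^\\$", map$dollar, out)
  # R strings cannot carry embedded NUL; strip any escaped representation
  # defensively if a replacement was configured
  if (nzchar(map$nul)) out <- gsub(map$nul, "", out, fixed = TRUE)
  out
}

#' Sanitize every object key of a document
#'
#' Walks the document and rewrites keys at every depth; values are
#' untouched. Two distinct keys that collide after sanitization raise an
#' error naming both.
#'
#' @param doc A `jobj` / `jarr` / string document.
#' @param map Sanitization map.
#' @return The sanitized document.
#' @export
sanitize_document <- function(doc, map = default_sanitization_map()) {
  # explicit work stack; rebuilt bottom-up via a parallel result stack
  san1 <- function(x) {
    if (is.character(x)) return(x)
    if (is_jarr(x)) return(jarr_from(lapply(unclass(x), san1)))
    if (is_jobj(x)) {
      old <- names(x)
      new <- vapply(old, sanitize_field_name, "", map = map, USE.NAMES = FALSE)
      dup <- which(duplicated(new))
      if (length(dup) > 0L) {
        d <- new[dup[1L]]
        both <- old[new == d]
        rdf2json_error(sprintf(
          "keys '%s' and '%s' collide after sanitization ('%s')",
          both[1L], both[2L], d), "rdf2json_collision_error")
      }
      return(jobj_from(setNames(lapply(unclass(x), san1), new)))
    }
    rdf2json_error("unsupported JSON value", "rdf2json_contract_error")
  }
  san1(doc)
}

forbidden_key <- function(k) {
  grepl(".", k, fixed = TRUE) | startsWith(k, "$")
}

assert_sanitized <- function(doc) {
  chk <- function(x) {
    if (is_jobj(x)) {
      bad <- names(x)[forbidden_key(names(x))]
      if (length(bad) > 0L)
        rdf2json_error(sprintf("unsanitized field name '%s'; run sanitize_document first",
                               bad[1L]), "rdf2json_contract_error")
      lapply(unclass(x), chk)
    } else if (is_jarr(x)) {
      lapply(unclass(x), chk)
    }
    invisible(NULL)
  }
  chk(doc)
}

#' Write a MongoDB import file (JSON Lines)
#'
#' One minified JSON document per line, one line per resource: the
#' resource object augmented with a leading `"uri"` field holding the
#' resource key, and (with `embed_ns = TRUE`) an `"@ns"` field carrying the
#' namespace table. The document must already be sanitized.
#'
#' @param doc A sanitized root document (from [migrate_graph], then
#'   [sanitize_document]).
#' @param path Output path (conventionally `.jsonl`).
#' @param embed_ns Embed the namespace map into each record under `"@ns"`.
#' @return Number of lines written (= number of resources).
#' @export
write_import_file <- function(doc, path, embed_ns = FALSE) {
  assert_sanitized(doc)
  resources <- doc[["resources"]]
  ns <- doc[["namespaces"]]
  if (is.null(resources))
    rdf2json_error("document has no 'resources' member", "rdf2json_contract_error")
  lines <- character(length(resources))
  keys <- names(resources)
  for (i in seq_along(resources)) {
    rec <- c(list(uri = keys[i]),
             if (embed_ns) list("@ns" = ns),
             unclass(resources[[i]]))
    lines[i] <- json_serialize(jobj_from(rec), "minified")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0L)
    writeBin(charToRaw(enc2utf8(paste0(paste(lines, collapse = "\n"), "\n"))), con)
  length(lines)
}

#' Build the mongoimport command line
#'
#' @param db Database name.
#' @param coll Collection name.
#' @param file Path to the import file.
#' @return The command string.
#' @export
build_import_command <- function(db, coll, file) {
  for (x in list(db = db, coll = coll))
    if (!is.character(x) || length(x) != 1L || !nzchar(x))
      rdf2json_error("database and collection names must be non-empty",
                     "rdf2json_validation_error")
  q <- function(s) if (grepl("[[:space:]]", s)) shQuote(s) else s
  sprintf("mongoimport -d %s -c %s --file %s", q(db), q(coll), q(file))
}
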